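#' Quality-control filtering of observer transects
#'
#' Opportunistic observer transects carry no survey design, so implausible
#' records are removed in three ordered steps before analysis:
#' 1. length/speed plausibility - the geodesic start-end distance of a
#'    15-minute transect must lie in a credible band (default 1.35-5.40 km,
#'    i.e. average vessel speeds of 5.40-21.60 km/h);
#' 2. sea state - transects at Beaufort above a maximum (default 3) are
#'    discarded because detectability collapses in rough seas;
#' 3. spatial core - a bivariate kernel density estimate of transect
#'    midpoints (reference bandwidth) defines a 95% probability contour and
#'    transects outside it are treated as spatial outliers.
#'
#' @name qc
NULL

#' Average speed implied by a transect length and duration
#'
#' @param length_km transect length (km).
#' @param duration_min duration in minutes (default 15).
#' @return speed in km/h.
#' @export
#' @examples
#' speed_of(1.35) # 5.40 km/h
#' speed_of(5.40) # 21.60 km/h
speed_of <- function(length_km, duration_min = 15) {
  if (any(duration_min <= 0)) stop_config("duration_min must be > 0")
  length_km / (duration_min / 60)
}

#' Geodesic start-end length of transects, km
#' @param transects transect table with lon/lat start and end columns.
#' @return numeric vector of great-circle lengths (km); NA when coordinates
#'   are missing.
#' @export
geodesic_length_km <- function(transects) {
  ok <- stats::complete.cases(transects[, c("lon_start", "lat_start",
                                            "lon_end", "lat_end")])
  out <- rep(NA_real_, nrow(transects))
  if (any(ok)) {
    out[ok] <- geosphere::distGeo(
      as.matrix(transects[ok, c("lon_start", "lat_start")]),
      as.matrix(transects[ok, c("lon_end", "lat_end")])
    ) / 1000
  }
  out
}

#' Filter transects on plausible length (step 1)
#'
#' Keeps transects whose length lies in the closed interval
#' [min_km, max_km]. Records with missing coordinates/length are rejected.
#'
#' @param transects transect table.
#' @param min_km,max_km inclusive plausibility bounds (km).
#' @param use_geodesic recompute lengths from coordinates (default uses the
#'   `length_km` column when present and finite).
#' @return the retained subset.
#' @export
length_filter <- function(transects, min_km = 1.35, max_km = 5.40,
                          use_geodesic = FALSE) {
  len <- transects$length_km
  if (use_geodesic || is.null(len)) len <- geodesic_length_km(transects)
  keep <- !is.na(len) & len >= min_km & len <= max_km
  transects[keep, , drop = FALSE]
}

#' Filter transects on sea state (step 2)
#'
#' @param transects transect table.
#' @param max_beaufort maximum retained Beaufort (default 3, inclusive).
#' @return the retained subset.
#' @export
beaufort_filter <- function(transects, max_beaufort = 3) {
  keep <- !is.na(transects$beaufort) & transects$beaufort <= max_beaufort
  transects[keep, , drop = FALSE]
}

#' Kernel-density spatial core (step 3)
#'
#' Projects midpoints to a local equal-area plane, computes a bivariate
#' Gaussian kernel density on a grid with the normal-scale ("reference")
#' bandwidth per axis, and finds the density threshold whose super-level set
#' encloses the requested probability mass. The mask and its area (km^2) are
#' returned together with everything needed to test points for inclusion.
#'
#' @param lon,lat transect midpoint coordinates (decimal degrees).
#' @param level probability mass to enclose (default 0.95; `level >= 1` keeps
#'   everything).
#' @param grid_n grid resolution per axis (default 512).
#' @return object of class `kde_mask` with elements `x`, `y`, `z` (grid),
#'   `threshold`, `area_km2`, `level`, `h` (bandwidths, km) and the projection
#'   `origin`.
#' @export
kde_core <- function(lon, lat, level = 0.95, grid_n = 512L) {
  ok <- !is.na(lon) & !is.na(lat)
  lon <- lon[ok]; lat <- lat[ok]
  if (length(lon) < 50) stop_config("kde_core needs >= 50 points")
  pr <- project_equal_area(lon, lat)
  if (stats::sd(pr$x) == 0 || stats::sd(pr$y) == 0) {
    stop_config("zero-variance point set")
  }
  n <- length(pr$x)
  ## normal-scale reference bandwidth per axis for a 2-D Gaussian kernel
  hx <- stats::sd(pr$x) * n^(-1 / 6)
  hy <- stats::sd(pr$y) * n^(-1 / 6)
  lims <- c(range(pr$x) + c(-3, 3) * hx, range(pr$y) + c(-3, 3) * hy)
  ## MASS::kde2d uses a kernel sd of h/4
  kd <- MASS::kde2d(pr$x, pr$y, h = 4 * c(hx, hy), n = grid_n, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  zv <- as.vector(kd$z)
  total <- sum(zv) * cell
  if (level >= 1) {
    threshold <- 0
    area <- length(zv) * cell
  } else {
    ord <- order(zv, decreasing = TRUE)
    cum <- cumsum(zv[ord]) * cell
    idx <- which(cum >= level * total)[1]
    threshold <- zv[ord][idx]
    area <- idx * cell
  }
  structure(
    list(x = kd$x, y = kd$y, z = kd$z, threshold = threshold,
         area_km2 = area, level = level, h = c(hx, hy), origin = pr$origin),
    class = "kde_mask"
  )
}

## bilinear interpolation of the KDE grid at projected points
.kde_density_at <- function(mask, x, y) {
  gx <- mask$x; gy <- mask$y
  ix <- findInterval(x, gx, all.inside = TRUE)
  iy <- findInterval(y, gy, all.inside = TRUE)
  out <- numeric(length(x))
  inside <- x >= gx[1] & x <= gx[length(gx)] & y >= gy[1] & y <= gy[length(gy)]
  tx <- (x - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (y - gy[iy]) / (gy[iy + 1] - gy[iy])
  z <- mask$z
  v <- (1 - tx) * (1 - ty) * z[cbind(ix, iy)] +
    tx * (1 - ty) * z[cbind(ix + 1, iy)] +
    (1 - tx) * ty * z[cbind(ix, iy + 1)] +
    tx * ty * z[cbind(ix + 1, iy + 1)]
  out[inside] <- v[inside]
  out
}

#' Test points for inclusion in a KDE core mask
#' @param mask a [kde_core()] result.
#' @param lon,lat points to test (decimal degrees).
#' @return logical vector.
#' @export
point_in_mask <- function(mask, lon, lat) {
  pr <- project_equal_area(lon, lat, origin = mask$origin)
  .kde_density_at(mask, pr$x, pr$y) >= mask$threshold
}

#' Midpoint positions of transects (decimal degrees)
#' @param transects transect table.
#' @return matrix with columns `lon`, `lat`.
#' @export
transect_midpoints <- function(transects) {
  mp <- geosphere::midPoint(
    as.matrix(transects[, c("lon_start", "lat_start")]),
    as.matrix(transects[, c("lon_end", "lat_end")])
  )
  colnames(mp) <- c("lon", "lat")
  mp
}

#' Filter transects to the KDE spatial core (step 3)
#' @param transects transect table.
#' @param mask a [kde_core()] mask.
#' @return the retained subset (midpoint inside the mask).
#' @export
spatial_filter <- function(transects, mask) {
  mp <- transect_midpoints(transects)
  transects[point_in_mask(mask, mp[, "lon"], mp[, "lat"]), , drop = FALSE]
}

#' QC configuration
#' @param min_length_km,max_length_km length plausibility bounds (km).
#' @param max_beaufort maximum retained Beaufort.
#' @param kde_level KDE core probability level.
#' @param kde_grid_n KDE grid resolution.
#' @export
qc_config <- function(min_length_km = 1.35, max_length_km = 5.40,
                      max_beaufort = 3, kde_level = 0.95, kde_grid_n = 512L) {
  list(min_length_km = min_length_km, max_length_km = max_length_km,
       max_beaufort = max_beaufort, kde_level = kde_level,
       kde_grid_n = kde_grid_n)
}

#' Run the three QC filters in order and report attrition
#'
#' Applies length, Beaufort and spatial-core filtering (in that order), drops
#' sightings whose parent transect was removed, and assembles a `qc_report`
#' with per-step counts and a per-year effort table.
#'
#' @param transects transect table.
#' @param sightings sighting table (may be empty).
#' @param config a [qc_config()].
#' @return list with `transects`, `sightings`, `report` (class `qc_report`)
#'   and the KDE `mask`.
#' @export
qc_pipeline <- function(transects, sightings, config = qc_config()) {
  n0 <- nrow(transects)
  t1 <- length_filter(transects, config$min_length_km, config$max_length_km)
  t2 <- beaufort_filter(t1, config$max_beaufort)
  mp <- transect_midpoints(t2)
  mask <- kde_core(mp[, "lon"], mp[, "lat"], level = config$kde_level,
                   grid_n = config$kde_grid_n)
  t3 <- spatial_filter(t2, mask)
  s3 <- sightings[sightings$transect_id %in% t3$transect_id, , drop = FALSE]

  eff <- do.call(rbind, lapply(split(t3, t3$year), function(d) {
    data.frame(year = d$year[1], n_transects = nrow(d),
               total_km = sum(d$length_km), mean_length_km = mean(d$length_km))
  }))
  rownames(eff) <- NULL

  report <- structure(
    list(
      n_input = n0, n_after_length = nrow(t1), n_after_beaufort = nrow(t2),
      n_after_kde = nrow(t3),
      dropped = c(length = n0 - nrow(t1), beaufort = nrow(t1) - nrow(t2),
                  spatial = nrow(t2) - nrow(t3)),
      kde_area_km2 = mask$area_km2,
      effort_by_year = eff,
      n_sightings_input = nrow(sightings), n_sightings_kept = nrow(s3)
    ),
    class = "qc_report"
  )
  list(transects = t3, sightings = s3, report = report, mask = mask)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Transect QC report\n")
  cat(sprintf("  input                : %d transects\n", x$n_input))
  cat(sprintf("  after length filter  : %d (-%d)\n", x$n_after_length, x$dropped["length"]))
  cat(sprintf("  after Beaufort filter: %d (-%d)\n", x$n_after_beaufort, x$dropped["beaufort"]))
  cat(sprintf("  after KDE core       : %d (-%d)\n", x$n_after_kde, x$dropped["spatial"]))
  cat(sprintf("  95%% core area        : %.0f km^2\n", x$kde_area_km2))
  cat(sprintf("  sightings kept       : %d of %d\n", x$n_sightings_kept, x$n_sightings_input))
  invisible(x)
}
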