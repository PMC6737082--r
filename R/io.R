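#' File formats and pipeline orchestration
#'
#' Delimited-text readers with validation (comma-separated, '.' decimal, NA
#' as empty field; coordinates WGS84 decimal degrees; angles in degrees;
#' distances metric), and a `run_all()` orchestrator that executes
#' QC -> detection -> ZIP-GAM -> bootstrap -> trend and writes all artifacts
#' with a provenance hash.
#'
#' @name cli_io
NULL

.read_csv <- function(path, what) {
  if (!file.exists(path)) stop_config("%s file not found: %s", what, path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

.validate_rows <- function(df, checks, what) {
  bad <- character(0)
  for (nm in names(checks)) {
    viol <- which(!checks[[nm]](df))
    if (length(viol)) {
      bad <- c(bad, sprintf("%s: line %s: %s", what,
                            paste(utils::head(viol, 5) + 1L, collapse = ","), nm))
    }
  }
  if (length(bad)) stop_config("validation failed\n%s", paste(bad, collapse = "\n"))
  df
}

#' Read and validate a transect table
#' @param path CSV path (see the package README for the column schema).
#' @return validated data.frame.
#' @export
read_transects <- function(path) {
  df <- .read_csv(path, "transects")
  assert_cols(df, c("transect_id", "year", "month", "time_block",
                    "lat_start", "lon_start", "lat_end", "lon_end",
                    "observer_id", "vessel_id", "beaufort", "glare",
                    "visibility", "length_km", "speed_kmh", "sst_c",
                    "dcoast_km", "d500_km", "d1000_km", "depth_m",
                    "slope_deg", "npp_mgc_m2_d", "sshd_m"), "transects")
  .validate_rows(df, list(
    "length_km must be > 0" = function(d) is.na(d$length_km) | d$length_km > 0,
    "beaufort must be 0..6" = function(d) is.na(d$beaufort) |
      (d$beaufort >= 0 & d$beaufort <= 6),
    "count must be >= 0" = function(d) is.null(d$count) | is.na(d$count) | d$count >= 0,
    "start and end coordinates must differ" = function(d)
      is.na(d$lat_start) | !(d$lat_start == d$lat_end & d$lon_start == d$lon_end)
  ), "transects")
}

#' Read and validate a sighting table
#' @param path CSV path with columns sighting_id, transect_id, radial_m,
#'   angle_deg, n_individuals.
#' @return validated data.frame.
#' @export
read_sightings <- function(path) {
  df <- .read_csv(path, "sightings")
  assert_cols(df, c("sighting_id", "transect_id", "radial_m", "angle_deg",
                    "n_individuals"), "sightings")
  .validate_rows(df, list(
    "radial_m must be > 0" = function(d) d$radial_m > 0,
    "angle_deg must be in [0, 180]" = function(d)
      d$angle_deg >= 0 & d$angle_deg <= 180,
    "n_individuals must be >= 1" = function(d) d$n_individuals >= 1
  ), "sightings")
}

#' Read and validate an annual nest-count table
#' @param path CSV path with columns year, nest_count.
#' @return validated data.frame.
#' @export
read_nests <- function(path) {
  df <- .read_csv(path, "nests")
  assert_cols(df, c("year", "nest_count"), "nests")
  .validate_rows(df, list(
    "nest_count must be > 0" = function(d) d$nest_count > 0,
    "year must not repeat" = function(d) !duplicated(d$year)
  ), "nests")
}

#' Write a synthetic dataset to the package's CSV schemas
#' @param dataset a [simulate_fleet()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (transects, sightings, truth JSON).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "transects.csv")
  sp <- file.path(dir, "sightings.csv")
  jp <- file.path(dir, "truth.json")
  utils::write.csv(dataset$transects, tp, row.names = FALSE, na = "")
  sg <- dataset$sightings[, c("sighting_id", "transect_id", "radial_m",
                              "angle_deg", "n_individuals")]
  utils::write.csv(sg, sp, row.names = FALSE, na = "")
  jsonlite::write_json(dataset$truth, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(transects = tp, sightings = sp, truth = jp))
}

## KDE mask -> GeoJSON (WGS84) via contour lines at the mask threshold
.mask_geojson <- function(mask) {
  lines <- grDevices::contourLines(mask$x, mask$y, mask$z,
                                   levels = max(mask$threshold, 1e-300))
  cl0 <- cos(mask$origin$lat0 * DEG2RAD)
  polys <- lapply(lines, function(cl) {
    lon <- mask$origin$lon0 + cl$x / (EARTH_RADIUS_KM * cl0) / DEG2RAD
    lat <- asin(pmin(pmax(cl$y * cl0 / EARTH_RADIUS_KM, -1), 1)) / DEG2RAD
    ring <- cbind(lon, lat)
    rbind(ring, ring[1, , drop = FALSE])   # close the ring
  })
  list(
    type = "Feature",
    properties = list(level = mask$level, area_km2 = mask$area_km2),
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(polys, list))
  )
}

#' Pipeline run configuration
#'
#' @param transects,sightings,nests input CSV paths (`nests` may be NULL; the
#'   trend stage is then skipped).
#' @param out_dir output directory.
#' @param qc a [qc_config()]; @param smear a [smear_config()];
#' @param bins a [bin_scheme()]; @param spec a [model_spec()].
#' @param detection_candidates candidate list for [fit_detection()].
#' @param n_boot bootstrap replicates (0 skips the bootstrap).
#' @param max_lag maximum lag for the trend stage.
#' @param seed master seed.
#' @export
run_config <- function(transects, sightings, nests = NULL, out_dir = ".",
                       qc = qc_config(), smear = smear_config(),
                       bins = bin_scheme(), spec = model_spec(),
                       detection_candidates = default_detection_candidates(),
                       n_boot = 1000L, max_lag = 12L, seed = 1L) {
  for (p in c(transects, sightings, nests)) {
    if (!is.null(p) && !file.exists(p)) stop_config("input file not found: %s", p)
  }
  structure(list(transects = transects, sightings = sightings, nests = nests,
                 out_dir = out_dir, qc = qc, smear = smear, bins = bins,
                 spec = spec, detection_candidates = detection_candidates,
                 n_boot = n_boot, max_lag = max_lag, seed = seed),
            class = "run_config")
}

#' Run the full pipeline and write all artifacts
#'
#' Executes QC -> detection -> ZIP-GAM (backward selection) -> bootstrap ->
#' trend and writes `qc_report.json`, `detection_model.json`,
#' `abundance_index.csv`, `ccf.csv`, `kde_core.geojson` and `run_log.txt`
#' into the configured output directory. Column headers carry units. Every
#' artifact records the configuration hash for provenance.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every fitted object and the artifact paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- fnv1a_hash(config[c("qc", "smear", "bins", "spec", "n_boot",
                                  "max_lag", "seed")])
  log_lines <- c(
    sprintf("turtleindex run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("R %s, turtleindex %s", getRversion(),
            as.character(utils::packageVersion("turtleindex"))),
    sprintf("seed %d, config hash %s", config$seed, cfg_hash)
  )
  transects <- read_transects(config$transects)
  sightings <- read_sightings(config$sightings)

  qc <- qc_pipeline(transects, sightings, config$qc)
  rep <- qc$report
  jsonlite::write_json(
    c(unclass(rep), list(config_hash = cfg_hash)),
    file.path(config$out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(jsonlite::toJSON(.mask_geojson(qc$mask), auto_unbox = TRUE,
                              digits = 8),
             file.path(config$out_dir, "kde_core.geojson"))
  log_lines <- c(log_lines, sprintf("QC: %d -> %d transects", rep$n_input,
                                    rep$n_after_kde))

  binned <- bin_sightings(qc$sightings, qc$transects, config$smear, config$bins)
  dm <- fit_detection(binned, candidates = config$detection_candidates)
  gof <- tryCatch(gof_chisq(dm, binned), error = function(e) NULL)
  jsonlite::write_json(
    list(key = dm$key, adjustment = dm$adjustment,
         adj_coefs = dm$adj_coefs, covariates = dm$covars,
         scale_coefs = as.list(dm$scale_coefs), shape_b = dm$shape_b,
         truncation_m = dm$truncation_m, aic = dm$aic,
         p_by_stratum = as.list(dm$p_by_stratum), p_overall = dm$p_overall,
         gof = if (!is.null(gof)) gof[c("chi2", "df", "p")],
         config_hash = cfg_hash),
    file.path(config$out_dir, "detection_model.json"),
    auto_unbox = TRUE, digits = NA
  )
  log_lines <- c(log_lines, sprintf("detection: %s/%s p=%.3f", dm$key,
                                    dm$adjustment, dm$p_overall))

  p_hat <- predict_p(dm, qc$transects)
  ok <- is.finite(p_hat) & p_hat > 0
  tr <- qc$transects[ok, , drop = FALSE]
  sw_km <- strip_width(config$bins$truncation_m) / 1000
  off <- log(effective_area(tr$length_km, sw_km, p_hat[ok]))
  fit <- backward_select(tr, config$spec, off)
  ai <- annual_index(fit)
  log_lines <- c(log_lines,
                 sprintf("zipgam: terms %s", paste(fit$terms, collapse = "+")))

  boot <- NULL
  if (config$n_boot > 0) {
    boot <- bootstrap_pipeline(tr, qc$sightings[qc$sightings$transect_id %in%
                                                  tr$transect_id, ],
                               dm, fit, config$smear, config$bins,
                               n_reps = config$n_boot, seed = config$seed)
    m <- match(ai$year, boot$years)
    ai$bse <- boot$bse[m]
    ai$bci_lo <- boot$bci[m, 1]
    ai$bci_hi <- boot$bci[m, 2]
    log_lines <- c(log_lines, sprintf("bootstrap: %d reps, %d failed",
                                      boot$n_reps, boot$failures))
  } else {
    ai$bse <- ai$bci_lo <- ai$bci_hi <- NA_real_
  }
  idx_tab <- data.frame(
    year = ai$year, index_per_0p1km2 = ai$index, bse = ai$bse,
    bci_lo = ai$bci_lo, bci_hi = ai$bci_hi, config_hash = cfg_hash
  )
  utils::write.csv(idx_tab, file.path(config$out_dir, "abundance_index.csv"),
                   row.names = FALSE, na = "")

  cc <- NULL
  if (!is.null(config$nests) && file.exists(config$nests)) {
    nests <- read_nests(config$nests)
    cc <- cross_correlation(annual_series(ai$year, ai$index),
                            annual_series(nests$year, nests$nest_count),
                            max_lag = config$max_lag)
    utils::write.csv(
      data.frame(lag_yr = cc$lag, r = cc$r_by_lag, n = cc$n_by_lag,
                 config_hash = cfg_hash),
      file.path(config$out_dir, "ccf.csv"), row.names = FALSE, na = ""
    )
    log_lines <- c(log_lines, sprintf("trend: best lag %d yr (r=%.2f)",
                                      cc$best_lag,
                                      cc$r_by_lag[cc$lag == cc$best_lag]))
  } else {
    log_lines <- c(log_lines, "trend: skipped (no nest series provided)")
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(qc = qc, detection = dm, gof = gof, fit = fit,
                 annual_index = ai, bootstrap = boot, ccf = cc,
                 config_hash = cfg_hash, out_dir = config$out_dir))
}
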