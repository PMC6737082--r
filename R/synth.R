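#' Synthetic observer-program data with known truth
#'
#' The generator emulates the statistical structure of an opportunistic
#' fishery-observer sighting programme for oceanic-stage juvenile loggerheads:
#' 15-minute visual strip transects performed by tuna vessels, clustered in a
#' few fishing grounds, with Beaufort-dependent detectability, heaped angle and
#' distance measurements, excess zeros, observer random effects, a smooth
#' distance-to-coast effect and year-to-year density proportional to a lagged
#' nest-count series. The true generating parameters travel with the dataset
#' so that every downstream stage (QC, detection function, ZIP-GAM, bootstrap,
#' lag analysis) can be tested by parameter recovery.
#'
#' @name synth
NULL

#' Built-in synthetic annual nest-count series
#'
#' A fabricated stand-in for an index-beach nest-count series (synthetic, not
#' observed data): annual nest counts for 1989--2015 with a pronounced decline
#' of roughly 43\% between the late-1990s peak and 2006 followed by a recovery,
#' the qualitative pattern the abundance index is expected to track after a
#' lag. Values are deterministic.
#'
#' @return data.frame with columns `year` and `nest_count`.
#' @export
#' @examples
#' head(synthetic_nest_series())
synthetic_nest_series <- function() {
  data.frame(
    year = 1989:2015,
    nest_count = c(
      47600, 51200, 49100, 54400, 50900, 56600, 59300, 55700, 52800,
      61500, 59000, 60900, 53800, 51300, 47500, 42500, 39000, 35000,
      41000, 44500, 40100, 47800, 50700, 58200, 55100, 53000, 65800
    )
  )
}

#' Configuration for the synthetic fleet generator
#'
#' @param n_years number of survey years (default 15).
#' @param transects_per_year_mean expected number of 15-minute transects per
#'   year (default 1184, the scale of a mid-size observer programme).
#' @param start_year first survey calendar year.
#' @param nest_series data.frame (`year`, `nest_count`) driving the true annual
#'   density; must cover `start_year - lag_years` through the last survey year.
#' @param lag_years lag (years) between the nest series and in-water density:
#'   density in year y is proportional to nests in year y - lag_years.
#' @param base_density mean true density, turtles per km^2.
#' @param sigma0_m hazard-rate detection scale (m) at Beaufort 0.
#' @param hazard_shape_b hazard-rate shape exponent (> 1).
#' @param beaufort_sigma_decay multiplicative scale factor per Beaufort step,
#'   in (0, 1]: sigma(bft) = sigma0_m * beaufort_sigma_decay^bft.
#' @param zero_inflation probability of a structural zero, in [0, 1).
#' @param observer_sd SD of log-scale observer random effects.
#' @param heaping list with `angle_round_deg` and `dist_round_m` (set either to
#'   0 to disable heaping of that measurement).
#' @param dcoast_effect,sst_effect log-scale effect sizes of the fabricated
#'   distance-to-coast and sea-surface-temperature fields (all other fabricated
#'   covariates have zero effect).
#' @param mean_group_size mean turtles per sighted group (>= 1); the group-size
#'   process is a knob only, unvalidated against field data.
#' @param max_sight_range_m maximum perpendicular distance (m) at which a
#'   turtle can be generated (beyond the 100 m analysis truncation on purpose).
#' @param seed integer RNG seed; a fixed seed reproduces the dataset exactly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_years = 15L,
                       transects_per_year_mean = 1184L,
                       start_year = 2001L,
                       nest_series = synthetic_nest_series(),
                       lag_years = 3L,
                       base_density = 0.4,
                       sigma0_m = 20,
                       hazard_shape_b = 3,
                       beaufort_sigma_decay = 0.64,
                       zero_inflation = 0.4,
                       observer_sd = 0.3,
                       heaping = list(angle_round_deg = 10, dist_round_m = 10),
                       dcoast_effect = -0.8,
                       sst_effect = -0.08,
                       mean_group_size = 1.05,
                       max_sight_range_m = 300,
                       seed = 1L) {
  if (n_years < 1) stop_config("n_years must be >= 1")
  if (base_density < 0) stop_config("base_density must be non-negative")
  if (transects_per_year_mean < 1) stop_config("transects_per_year_mean must be >= 1")
  if (sigma0_m <= 0) stop_config("sigma0_m must be positive")
  if (hazard_shape_b <= 1) stop_config("hazard_shape_b must be > 1")
  if (beaufort_sigma_decay <= 0 || beaufort_sigma_decay > 1) {
    stop_config("beaufort_sigma_decay must be in (0, 1]")
  }
  if (zero_inflation < 0 || zero_inflation >= 1) stop_config("zero_inflation must be in [0, 1)")
  if (observer_sd < 0) stop_config("observer_sd must be >= 0")
  if (mean_group_size < 1) stop_config("mean_group_size must be >= 1")
  if (lag_years < 0) stop_config("lag_years must be >= 0")
  assert_cols(nest_series, c("year", "nest_count"), "nest_series")
  if (any(nest_series$nest_count <= 0)) stop_config("nest_series must be strictly positive")
  need <- (start_year - lag_years):(start_year + n_years - 1 - lag_years)
  if (!all(need %in% nest_series$year)) {
    stop_config("nest_series must cover years %d..%d", min(need), max(need))
  }
  structure(
    list(
      n_years = as.integer(n_years),
      transects_per_year_mean = transects_per_year_mean,
      start_year = as.integer(start_year),
      nest_series = nest_series,
      lag_years = as.integer(lag_years),
      base_density = base_density,
      sigma0_m = sigma0_m,
      hazard_shape_b = hazard_shape_b,
      beaufort_sigma_decay = beaufort_sigma_decay,
      zero_inflation = zero_inflation,
      observer_sd = observer_sd,
      heaping = heaping,
      dcoast_effect = dcoast_effect,
      sst_effect = sst_effect,
      mean_group_size = mean_group_size,
      max_sight_range_m = max_sight_range_m,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' True annual densities implied by a simulation configuration
#'
#' Density in survey year y is proportional to the nest count in year
#' y - lag_years, rescaled so that the mean over the survey period equals
#' `base_density` (turtles per km^2).
#'
#' @param cfg a [sim_config()].
#' @return named numeric vector of per-year true densities (names are survey
#'   years).
#' @export
annual_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  src <- years - cfg$lag_years
  nests <- cfg$nest_series$nest_count[match(src, cfg$nest_series$year)]
  dens <- cfg$base_density * nests / mean(nests)
  names(dens) <- years
  dens
}

## Fabricated island/fishing-ground cluster centres (lon, lat) inside the
## study box; transect positions concentrate around these.
.fleet_clusters <- function() {
  cbind(
    lon = c(-28.7, -27.1, -25.6, -31.2, -28.0),
    lat = c(38.5, 38.7, 37.8, 39.4, 38.0)
  )
}

#' Simulate an observer-program fleet season series
#'
#' Draws transects and sightings with the generative structure described in
#' [synth]: clustered positions with ~5\% spatial outliers, ~10\% of transect
#' lengths outside the plausible 1.35--5.40 km band, ~15\% of Beaufort states
#' above 3 (all three planted deliberately so the QC filters have work to do),
#' zero-inflated Poisson counts whose yearly mean follows [annual_truth()],
#' hazard-rate detection thinning with Beaufort-dependent scale, and heaping of
#' the recorded angles/distances to the nearest 10 degrees / 10 m.
#'
#' @param cfg a [sim_config()].
#' @return object of class `synthetic_dataset`: list with `transects`,
#'   `sightings` (data.frames in the package's file schemas) and `truth`
#'   (true annual densities, detection parameters, observer effects and
#'   planted-violation bookkeeping). `truth` exists for parameter-recovery
#'   tests only and is never used by the analysis stages.
#' @export
#' @examples
#' d <- simulate_fleet(sim_config(n_years = 2, transects_per_year_mean = 50, seed = 7))
#' nrow(d$transects)
simulate_fleet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dens <- annual_truth(cfg)
  years <- as.integer(names(dens))
  clusters <- .fleet_clusters()
  n_obs_pool <- 40L
  observers <- sprintf("obs%02d", seq_len(n_obs_pool))

  set.seed(cfg$seed)
  obs_eff <- stats::rnorm(n_obs_pool, 0, cfg$observer_sd)
  names(obs_eff) <- observers
  vessels <- sprintf("ves%02d", 1:25)

  w_sim_km <- cfg$max_sight_range_m / 1000
  sigma_by_bft <- cfg$sigma0_m * cfg$beaufort_sigma_decay^(0:5)

  tr_list <- vector("list", cfg$n_years)
  sg_list <- vector("list", cfg$n_years)
  planted <- c(length = 0L, beaufort = 0L, spatial = 0L)
  sid <- 0L

  for (yi in seq_len(cfg$n_years)) {
    ## one reproducible sub-stream per survey year
    set.seed(cfg$seed + 7919L * yi)
    yr <- years[yi]
    n_t <- max(2L, stats::rpois(1, cfg$transects_per_year_mean))

    month <- sample(5:11, n_t, replace = TRUE)
    time_block <- sample(c(900L, 1100L, 1300L, 1500L, 1700L, 1900L), n_t, replace = TRUE)

    is_outlier <- stats::runif(n_t) < 0.05
    k <- sample(nrow(clusters), n_t, replace = TRUE)
    lon <- clusters[k, "lon"] + stats::rnorm(n_t, 0, 0.35)
    lat <- clusters[k, "lat"] + stats::rnorm(n_t, 0, 0.30)
    lon[is_outlier] <- stats::runif(sum(is_outlier), -34, -22)
    lat[is_outlier] <- stats::runif(sum(is_outlier), 34.5, 41.5)

    ## ~90% plausible lengths, ~10% planted violations (too short or too long)
    bad_len <- stats::runif(n_t) < 0.10
    len <- stats::rnorm(n_t, 3.82, 0.87)
    while (any(out <- !bad_len & (len < 1.35 | len > 5.40))) {
      len[out] <- stats::rnorm(sum(out), 3.82, 0.87)
    }
    n_bad <- sum(bad_len)
    if (n_bad) {
      short <- stats::runif(n_bad) < 0.5
      len[bad_len] <- ifelse(short,
        stats::runif(n_bad, 0.3, 1.30),
        stats::runif(n_bad, 5.45, 8.5)
      )
    }
    speed <- len / 0.25

    beaufort <- sample(0:5, n_t, replace = TRUE,
                       prob = c(0.22, 0.28, 0.22, 0.13, 0.09, 0.06))
    glare <- sample(c("none", "weak", "strong"), n_t, replace = TRUE,
                    prob = c(0.5, 0.35, 0.15))
    visibility <- sample(c("moderate", "good", "excellent"), n_t, replace = TRUE,
                         prob = c(0.2, 0.5, 0.3))
    obs_id <- sample(observers, n_t, replace = TRUE)
    ves_id <- sample(vessels, n_t, replace = TRUE)

    bearing <- stats::runif(n_t, 0, 360)
    endp <- geosphere::destPoint(cbind(lon, lat), bearing, len * 1000)

    ## fabricated smooth environmental fields
    dcl <- geosphere::distHaversine(
      cbind(rep(lon, each = nrow(clusters)), rep(lat, each = nrow(clusters))),
      clusters[rep(seq_len(nrow(clusters)), n_t), ]
    ) / 1000
    dcoast <- apply(matrix(dcl, nrow = nrow(clusters)), 2, min)
    sst <- 17 + 4 * sin(2 * pi * (month - 4.5) / 12) + stats::rnorm(n_t, 0, 0.6)
    depth <- pmax(50, 900 + 1400 * (1 - exp(-dcoast / 40)) + stats::rnorm(n_t, 0, 120))
    slope <- pmax(0.1, 12 * exp(-dcoast / 25) + stats::rnorm(n_t, 0, 1.5))
    d500 <- pmax(0.1, 0.55 * dcoast + stats::rnorm(n_t, 0, 2))
    d1000 <- pmax(0.2, 0.80 * dcoast + stats::rnorm(n_t, 0, 2.5))
    npp <- pmax(30, 620 - 18 * sst + stats::rnorm(n_t, 0, 12))
    sshd <- stats::rnorm(n_t, 0, 0.08)

    ## expected number of individuals truly present in the simulated strip
    cov_eff <- cfg$dcoast_effect * exp(-dcoast / 8) + cfg$sst_effect * (sst - 17)
    cov_eff <- cov_eff - (cfg$dcoast_effect * 0.18 + 0)  # approx field-mean centring
    lambda_true <- dens[yi] * len * 2 * w_sim_km *
      exp(obs_eff[obs_id] + cov_eff)

    structural_zero <- stats::runif(n_t) < cfg$zero_inflation
    g_mean <- cfg$mean_group_size
    n_groups <- ifelse(structural_zero, 0L, stats::rpois(n_t, lambda_true / g_mean))

    counts <- integer(n_t)
    tid <- sprintf("%d_t%05d", yr, seq_len(n_t))

    tot_groups <- sum(n_groups)
    if (tot_groups > 0) {
      parent <- rep.int(seq_len(n_t), n_groups)
      d_true <- stats::runif(tot_groups, 0, cfg$max_sight_range_m)
      sig <- sigma_by_bft[beaufort[parent] + 1L]
      p_det <- hazard_rate_g(d_true, sig, cfg$hazard_shape_b)
      det <- stats::runif(tot_groups) < p_det
      if (any(det)) {
        parent <- parent[det]
        d_det <- d_true[det]
        nd <- length(d_det)
        gsize <- 1L + stats::rpois(nd, g_mean - 1)
        ## angle uniform on (0, 180), resampled while the implied radial
        ## distance would exceed a physical sighting range
        theta <- stats::runif(nd, 0, 180)
        r <- d_det / sin(theta * DEG2RAD)
        while (any(fix <- !is.finite(r) | r > 2000)) {
          theta[fix] <- stats::runif(sum(fix), 0, 180)
          r[fix] <- d_det[fix] / sin(theta[fix] * DEG2RAD)
        }
        ar <- cfg$heaping$angle_round_deg
        dr <- cfg$heaping$dist_round_m
        theta_rec <- if (ar > 0) round(theta / ar) * ar else theta
        ## recorded distances are never 0 m: a heaped value that would round
        ## to zero is recorded at the first heap point instead
        r_rec <- if (dr > 0) pmax(dr, round(r / dr) * dr) else r
        counts <- as.integer(tapply(gsize, factor(parent, levels = seq_len(n_t)), sum))
        counts[is.na(counts)] <- 0L
        sg_list[[yi]] <- data.frame(
          sighting_id = sprintf("s%07d", sid + seq_len(nd)),
          transect_id = tid[parent],
          radial_m = r_rec,
          angle_deg = theta_rec,
          n_individuals = gsize,
          true_perp_m = d_det,
          true_radial_m = r,
          true_angle_deg = theta,
          stringsAsFactors = FALSE
        )
        sid <- sid + nd
      }
    }

    tr_list[[yi]] <- data.frame(
      transect_id = tid, year = yr, month = month, time_block = time_block,
      lat_start = lat, lon_start = lon,
      lat_end = endp[, "lat"], lon_end = endp[, "lon"],
      observer_id = obs_id, vessel_id = ves_id,
      beaufort = beaufort, glare = glare, visibility = visibility,
      length_km = len, speed_kmh = speed,
      sst_c = sst, dcoast_km = dcoast, d500_km = d500, d1000_km = d1000,
      depth_m = depth, slope_deg = slope, npp_mgc_m2_d = npp, sshd_m = sshd,
      count = counts,
      stringsAsFactors = FALSE
    )
    planted["length"] <- planted["length"] + sum(len < 1.35 | len > 5.40)
    planted["beaufort"] <- planted["beaufort"] + sum(beaufort > 3)
    planted["spatial"] <- planted["spatial"] + sum(is_outlier)
  }

  transects <- do.call(rbind, tr_list)
  sightings <- if (length(sg <- Filter(Negate(is.null), sg_list))) {
    do.call(rbind, sg)
  } else {
    data.frame(
      sighting_id = character(), transect_id = character(),
      radial_m = numeric(), angle_deg = numeric(), n_individuals = integer(),
      true_perp_m = numeric(), true_radial_m = numeric(), true_angle_deg = numeric(),
      stringsAsFactors = FALSE
    )
  }
  rownames(transects) <- rownames(sightings) <- NULL

  structure(
    list(
      transects = transects,
      sightings = sightings,
      truth = list(
        annual_density = dens,
        detection_params = list(
          key = "hazard_rate", sigma0_m = cfg$sigma0_m, b = cfg$hazard_shape_b,
          beaufort_sigma_decay = cfg$beaufort_sigma_decay,
          sigma_by_beaufort = sigma_by_bft
        ),
        observer_effects = obs_eff,
        zero_inflation = cfg$zero_inflation,
        planted_violations = planted
      ),
      cfg = cfg
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic observer-program dataset\n")
  cat(sprintf("  %d transects, %d sightings, years %d-%d\n",
              nrow(x$transects), nrow(x$sightings),
              min(x$transects$year), max(x$transects$year)))
  cat(sprintf("  true mean density %.3f turtles/km^2, zero inflation %.2f\n",
              mean(x$truth$annual_density), x$truth$zero_inflation))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d yr from %d, ~%s transects/yr, density %.3g/km^2, lag %d yr, seed %d\n",
    x$n_years, x$start_year, format(x$transects_per_year_mean), x$base_density,
    x$lag_years, x$seed
  ))
  invisible(x)
}
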