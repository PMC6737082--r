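test_that("per-year resampling preserves counts and carries sightings along", {
  cfg <- sim_config(n_years = 3, transects_per_year_mean = 120, seed = 31)
  d <- simulate_fleet(cfg)
  rs <- resample_dataset(d$transects, d$sightings, seed = 1)
  expect_equal(table(rs$transects$year), table(d$transects$year))
  expect_false(anyDuplicated(rs$transects$transect_id) > 0)
  expect_true(all(rs$sightings$transect_id %in% rs$transects$transect_id))

  # one transect per year: resampling is the identity (up to relabelling)
  one <- d$transects[!duplicated(d$transects$year), ]
  rs1 <- resample_dataset(one, d$sightings[0, ], seed = 2)
  expect_equal(nrow(rs1$transects), nrow(one))
  expect_equal(rs1$transects$length_km, one$length_km)
})

test_that("expected multiplicity of any transect is one", {
  tr <- data.frame(transect_id = sprintf("t%02d", 1:30), year = 2001)
  sg <- data.frame(sighting_id = character(), transect_id = character())
  set.seed(9)
  mult <- replicate(10000, {
    rs <- resample_dataset(tr, sg)
    sum(startsWith(rs$transects$transect_id, "t01_"))
  })
  se <- sd(mult) / sqrt(length(mult))
  expect_lt(abs(mean(mult) - 1), 3 * se)
})

test_that("identical transects give zero bootstrap variance", {
  # 20 interchangeable transects per year: every resample refits identically
  tr <- do.call(rbind, lapply(2001:2003, function(yr) {
    data.frame(
      transect_id = sprintf("%d_%02d", yr, 1:20), year = yr, month = 7,
      time_block = 1300, lat_start = 38, lon_start = -28, lat_end = 38.02,
      lon_end = -28.03, observer_id = "obsA", vessel_id = "v1", beaufort = 1,
      glare = "none", visibility = "good", length_km = 3.8, speed_kmh = 15.2,
      sst_c = 20, dcoast_km = 25, d500_km = 12, d1000_km = 20, depth_m = 1500,
      slope_deg = 3, npp_mgc_m2_d = 250, sshd_m = 0, count = 1
    )
  }))
  sg <- data.frame(
    sighting_id = sprintf("s%03d", seq_len(nrow(tr))),
    transect_id = tr$transect_id, radial_m = 40, angle_deg = 60,
    n_individuals = 1
  )
  binned <- bin_sightings(sg, tr, smear_config())
  dm <- fit_detection(binned, candidates = cds_hazard_candidate())
  off <- log(effective_area(tr$length_km, 0.2, predict_p(dm, tr)))
  fit <- fit_zipgam(tr, model_spec(terms = "year", zi = "none"), off,
                    screen = FALSE)
  bt <- bootstrap_pipeline(tr, sg, dm, fit, n_reps = 12, seed = 4)
  expect_lt(max(bt$bse), 1e-8)
  expect_equal(bt$failures, 0)
})

test_that("bootstrap is reproducible and its percentiles are ordered", {
  cfg <- sim_config(n_years = 3, transects_per_year_mean = 300,
                    base_density = 2, seed = 47)
  pp <- pipeline_to_offsets(cfg, candidates = cds_hazard_candidate())
  fit <- fit_zipgam(pp$transects, model_spec(terms = "year", zi = "constant"),
                    pp$offset_log, screen = FALSE)
  b1 <- bootstrap_pipeline(pp$transects, pp$sightings, pp$detection, fit,
                           n_reps = 25, seed = 7)
  b2 <- bootstrap_pipeline(pp$transects, pp$sightings, pp$detection, fit,
                           n_reps = 25, seed = 7)
  expect_identical(b1$annual_index_reps, b2$annual_index_reps)

  med <- apply(b1$annual_index_reps, 2, median)
  expect_true(all(b1$bci[, 1] <= med + 1e-12))
  expect_true(all(med <= b1$bci[, 2] + 1e-12))
  expect_true(all(b1$bse >= 0))
})

test_that("bootstrap standard errors shrink roughly as one over root effort", {
  mk <- function(mult, seed) {
    cfg <- sim_config(n_years = 2, transects_per_year_mean = 400 * mult,
                      base_density = 2, seed = seed)
    pp <- pipeline_to_offsets(cfg, candidates = cds_hazard_candidate())
    fit <- fit_zipgam(pp$transects, model_spec(terms = "year", zi = "constant"),
                      pp$offset_log, screen = FALSE)
    bt <- bootstrap_pipeline(pp$transects, pp$sightings, pp$detection, fit,
                             n_reps = 80, seed = 5)
    mean(bt$bse / colMeans(bt$annual_index_reps))   # relative BSE
  }
  r1 <- mk(1, 7001)
  r4 <- mk(4, 7001)
  # factor-4 effort should roughly halve the relative BSE
  expect_gt(r1 / r4, 2 * 0.75)
  expect_lt(r1 / r4, 2 * 1.25)
})
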