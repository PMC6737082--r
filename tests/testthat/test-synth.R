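test_that("annual truth is the lagged, rescaled nest series", {
  cfg <- sim_config(n_years = 5, lag_years = 3, base_density = 0.5,
                    nest_series = flat_nests())
  expect_equal(unname(annual_truth(cfg)), rep(0.5, 5))

  ns <- flat_nests()
  ns$nest_count[ns$year == 2002] <- 100000   # doubles in 2002
  cfg2 <- sim_config(n_years = 8, lag_years = 3, start_year = 2001,
                     base_density = 0.5, nest_series = ns)
  tr <- annual_truth(cfg2)
  expect_equal(unname(which(tr == max(tr))), which(names(tr) == "2005"))
  expect_equal(unname(tr["2005"] / tr["2004"]), 2)

  cfg0 <- sim_config(n_years = 5, lag_years = 0, start_year = 2001,
                     base_density = 1, nest_series = ns)
  tr0 <- annual_truth(cfg0)
  expect_equal(unname(tr0["2002"] / tr0["2001"]), 2)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(base_density = -1), "base_density")
  expect_error(sim_config(n_years = 0), "n_years")
  expect_error(sim_config(zero_inflation = 1), "zero_inflation")
  expect_error(sim_config(nest_series = data.frame(year = 2000:2001,
                                                   nest_count = c(1, -1))),
               "positive")
})

test_that("fixed seed reproduces the dataset exactly; zero density yields no sightings", {
  cfg <- sim_config(n_years = 2, transects_per_year_mean = 120, seed = 33)
  d1 <- simulate_fleet(cfg)
  d2 <- simulate_fleet(cfg)
  expect_identical(d1$transects, d2$transects)
  expect_identical(d1$sightings, d2$sightings)

  d0 <- simulate_fleet(sim_config(n_years = 2, transects_per_year_mean = 100,
                                  base_density = 0, seed = 5))
  expect_gt(nrow(d0$transects), 0)
  expect_equal(nrow(d0$sightings), 0)
})

test_that("sightings reference existing transects and respect range invariants", {
  d <- simulate_fleet(sim_config(n_years = 3, transects_per_year_mean = 250,
                                 seed = 8))
  expect_true(all(d$sightings$transect_id %in% d$transects$transect_id))
  expect_true(all(d$sightings$radial_m > 0))
  expect_true(all(d$sightings$angle_deg >= 0 & d$sightings$angle_deg <= 180))
  expect_true(all(d$sightings$true_perp_m <= d$cfg$max_sight_range_m))
  # heaping marks: recorded values sit on the 10-unit lattice
  expect_true(all(d$sightings$radial_m %% 10 == 0))
  expect_true(all(d$sightings$angle_deg %% 10 == 0))
  # planted QC violations present in stated proportions (loose binomial bands)
  pl <- d$truth$planted_violations
  n <- nrow(d$transects)
  expect_gt(pl["length"] / n, 0.05); expect_lt(pl["length"] / n, 0.16)
  expect_gt(pl["beaufort"] / n, 0.09); expect_lt(pl["beaufort"] / n, 0.22)
})

test_that("zero-count fraction is at least the structural-zero probability", {
  for (zi in c(0, 0.3, 0.6)) {
    d <- simulate_fleet(sim_config(n_years = 2, transects_per_year_mean = 400,
                                   zero_inflation = zi, seed = 21))
    expect_gte(mean(d$transects$count == 0), zi)
  }
})

test_that("mean detected count per exposure matches density times average detectability", {
  # flat density, no zero inflation, no observer or covariate effects, no
  # heaping: E[count] = D * L * 2W * mean(g over U(0, W))
  cfg <- sim_config(
    n_years = 40, transects_per_year_mean = 300, start_year = 1990,
    nest_series = flat_nests(), lag_years = 0, base_density = 1,
    zero_inflation = 0, observer_sd = 0, dcoast_effect = 0, sst_effect = 0,
    mean_group_size = 1, heaping = list(angle_round_deg = 0, dist_round_m = 0),
    seed = 404
  )
  d <- simulate_fleet(cfg)
  W <- cfg$max_sight_range_m / 1000
  sig <- cfg$sigma0_m * cfg$beaufort_sigma_decay^(0:5)
  pbar <- vapply(sig, function(s)
    average_p(s, "hazard_rate", b = cfg$hazard_shape_b,
              w = cfg$max_sight_range_m), numeric(1))
  # pooled check (2 MC SE) and per-Beaufort check of the detection thinning
  expected <- sum(d$transects$length_km * 2 * W * pbar[d$transects$beaufort + 1])
  observed <- sum(d$transects$count)
  expect_lt(abs(observed - expected), 2 * sqrt(expected))
  for (bf in 0:3) {
    sub <- d$transects$beaufort == bf
    exp_bf <- sum(d$transects$length_km[sub]) * 2 * W * pbar[bf + 1]
    expect_lt(abs(sum(d$transects$count[sub]) - exp_bf), 2.5 * sqrt(exp_bf))
  }
})
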