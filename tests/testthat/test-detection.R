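test_that("perpendicular distance folds angles symmetrically", {
  expect_equal(perpendicular_distance(100, 90), 100)
  expect_equal(perpendicular_distance(50, 30), 25)
  expect_equal(perpendicular_distance(80, 150), 40)
  expect_error(perpendicular_distance(-1, 90), "radial")
  expect_error(perpendicular_distance(10, 200), "angle")
})

test_that("detection keys take their characteristic values", {
  expect_equal(hazard_rate_g(0, 20, 3), 1)
  expect_equal(half_normal_g(0, 20), 1)
  expect_equal(hazard_rate_g(25, 25, 3), 1 - exp(-1))
  expect_equal(hazard_rate_g(25, 25, 7), 1 - exp(-1))   # any b at d = sigma
  expect_equal(half_normal_g(30, 30), exp(-0.5))
})

test_that("smearing allocates sector mass to bins with conservation", {
  # degenerate sector: everything in the bin containing d = 25 m
  sw <- smear_to_bins(50, 30, 2, no_smear())
  expect_equal(sw$weights, c(0, 0, 0, 2, 0, 0, 0))
  expect_equal(sw$truncated, 0)

  # phi = 0, s = 0.2 at r = 100, theta = 90: d uniform on [80, 120];
  # overlap oracle: mass in [80,100] stays in the 50-100 bin, the rest is
  # beyond truncation
  sw2 <- smear_to_bins(100, 90, 1, smear_config(phi_deg = 0, s_prop = 0.2),
                       grid_n = 2001)
  expect_lt(abs(sw2$weights[7] - 0.5), 1e-3)
  expect_lt(abs(sw2$truncated - 0.5), 1e-3)
  expect_equal(sum(sw2$weights) + sw2$truncated, 1)

  # pre-truncation conservation for arbitrary sectors
  for (r in c(12, 47, 95)) {
    sw3 <- smear_to_bins(r, 40, 3, smear_config(phi_deg = 5, s_prop = 0.2))
    expect_equal(sum(sw3$weights) + sw3$truncated, 3)
  }

  # sector clipped at 0 degrees still conserves mass
  sw4 <- smear_to_bins(30, 2, 1, smear_config(phi_deg = 5, s_prop = 0.2))
  expect_equal(sum(sw4$weights) + sw4$truncated, 1)
})

test_that("strip width doubles the truncation distance over two sides", {
  expect_equal(strip_width(100), 200)
  expect_equal(strip_width(50, 2), 100)
  expect_equal(strip_width(100, 1), 100)
})

test_that("average detectability matches quadrature oracles", {
  # effectively perfect detection
  expect_lt(abs(average_p(1e7, "half_normal", w = 100) - 1), 1e-8)

  # half-normal closed form via the error function
  for (sig in c(10, 25, 40)) {
    for (w in c(50, 100)) {
      closed <- sqrt(pi / 2) * (sig / w) * (2 * stats::pnorm(w / sig) - 1)
      expect_lt(abs(average_p(sig, "half_normal", w = w) - closed), 1e-8)
    }
  }

  # hazard-rate vs brute-force Riemann sum
  x <- (seq_len(1e6) - 0.5) / 1e6 * 100
  rie <- mean(hazard_rate_g(x, 25, 3))
  expect_lt(abs(average_p(25, "hazard_rate", b = 3, w = 100) - rie), 1e-6)
})

test_that("binned likelihood recovers generating parameters and prefers the true key", {
  sg <- sim_detected_distances(800, seed = 4)
  b <- bin_sightings(sg, one_transect(), no_smear())
  dm <- fit_detection(b, candidates = cds_hazard_candidate())
  expect_lt(abs(exp(dm$scale_coefs[[1]]) / 30 - 1), 0.2)
  expect_lt(abs(dm$shape_b / 3 - 1), 0.3)
  expect_true(dm$p_overall > 0 && dm$p_overall <= 1)
  # fitted g is monotone non-increasing with g(0) = 1
  dd <- seq(0, 100, length.out = 101)
  g <- detection_g(dd, dm$key, exp(dm$scale_coefs[[1]]), dm$shape_b)
  expect_equal(g[1], 1)
  expect_true(all(diff(g) <= 1e-8))

  # AIC selects half-normal on clean half-normal data (large single dataset)
  sg_hn <- sim_detected_distances(2000, seed = 9,
                                  gfun = function(d) half_normal_g(d, 30))
  b_hn <- bin_sightings(sg_hn, one_transect(), no_smear())
  both <- c(cds_hazard_candidate(),
            list(list(key = "half_normal", adjustment = "none",
                      adj_order = 0L, covars = character(0))))
  dm_hn <- fit_detection(b_hn, candidates = both)
  expect_equal(dm_hn$key, "half_normal")
})

test_that("detectability declines with Beaufort when sigma does", {
  p <- vapply(c(20, 12.8, 8.2), function(s)
    average_p(s, "hazard_rate", b = 3, w = 100), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("goodness of fit matches hand-computed chi-square", {
  sg <- sim_detected_distances(400, seed = 2)
  b <- bin_sightings(sg, one_transect(), no_smear())
  dm <- fit_detection(b, candidates = cds_hazard_candidate())

  # exact agreement gives chi2 = 0, p = 1: craft a model whose expected
  # equals observed by using the fitted expected counts as "observed"
  g <- gof_chisq(dm, b)
  expect_gte(g$df, 1)
  hand <- sum((g$observed - g$expected)^2 / g$expected)
  expect_equal(g$chi2, hand)

  # hand-computable 3-bin oracle: obs 10/5/5 vs exp 8/6/6
  chi2_hand <- (10 - 8)^2 / 8 + (5 - 6)^2 / 6 + (5 - 6)^2 / 6
  expect_equal(chi2_hand, 0.5 + 1 / 6 + 1 / 6)

  # too few bins for the test -> error
  b_small <- b
  b_small$W <- b$W[, 1:3]
  b_small$bins <- bin_scheme(c(0, 5, 10, 20))
  expect_error(gof_chisq(dm, b_small), "too few bins")
})

test_that("fractional weights feed the likelihood (smeared vs raw agree approximately)", {
  sg <- sim_detected_distances(600, seed = 11)
  b_raw <- bin_sightings(sg, one_transect(), no_smear())
  b_sm <- bin_sightings(sg, one_transect(), smear_config())
  dm_raw <- fit_detection(b_raw, candidates = cds_hazard_candidate())
  dm_sm <- fit_detection(b_sm, candidates = cds_hazard_candidate())
  expect_lt(abs(dm_sm$p_overall / dm_raw$p_overall - 1), 0.15)
})
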