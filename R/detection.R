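#' Detection functions for binned line-transect distance sampling
#'
#' Tools for the sighting-probability stage: perpendicular distances, uniform
#' smearing of heaped angle/distance measurements into distance bins,
#' truncation, hazard-rate and half-normal detection keys with cosine or
#' polynomial adjustments, maximum-likelihood fitting of the binned
#' (conditional multinomial) likelihood with covariates on the scale
#' parameter, AIC model selection and a chi-square goodness-of-fit test.
#'
#' @name detection
NULL

#' Perpendicular distance from radial distance and sighting angle
#'
#' d = r * sin(theta). Angles beyond 90 degrees fold symmetrically (a sighting
#' at 150 degrees is as far abeam as one at 30 degrees).
#'
#' @param radial_m radial distance(s), metres, > 0.
#' @param angle_deg sighting angle(s), degrees in [0, 180].
#' @return perpendicular distance(s) in metres.
#' @export
#' @examples
#' perpendicular_distance(50, 30) # 25
perpendicular_distance <- function(radial_m, angle_deg) {
  if (any(radial_m <= 0, na.rm = TRUE)) stop_config("radial_m must be > 0")
  if (any(angle_deg < 0 | angle_deg > 180, na.rm = TRUE)) {
    stop_config("angle_deg must lie in [0, 180]")
  }
  radial_m * sin(angle_deg * DEG2RAD)
}

#' Hazard-rate detection key
#'
#' g(d) = 1 - exp(-(d/sigma)^(-b)); g(0) = 1 by continuity.
#' @param d perpendicular distance(s), metres.
#' @param sigma scale parameter (m), > 0; recycled against `d`.
#' @param b shape parameter, > 0 (values > 1 give the characteristic shoulder).
#' @export
hazard_rate_g <- function(d, sigma, b) {
  out <- 1 - exp(-(d / sigma)^(-b))
  out[d == 0] <- 1
  out
}

#' Half-normal detection key
#'
#' g(d) = exp(-d^2 / (2 sigma^2)).
#' @inheritParams hazard_rate_g
#' @export
half_normal_g <- function(d, sigma) exp(-d^2 / (2 * sigma^2))

## adjustment series values; cosine terms cos(k pi x / w) for k >= 2,
## simple polynomials (x/w)^(2k) for k >= 2
.adjustment_series <- function(d, w, type, order) {
  x <- d / w
  switch(type,
    none = NULL,
    cosine = vapply(seq_len(order) + 1L, function(k) cos(k * pi * x), numeric(length(x))),
    polynomial = vapply(seq_len(order) + 1L, function(k) x^(2 * k), numeric(length(x))),
    stop_config("unknown adjustment type '%s'", type)
  )
}

#' Evaluate a detection function g(d)
#'
#' Key function (hazard-rate or half-normal), optionally multiplied by a
#' series adjustment (cosine or simple polynomial) and renormalized so that
#' g(0) = 1.
#'
#' @param d perpendicular distances (m).
#' @param key `"hazard_rate"` or `"half_normal"`.
#' @param sigma scale (m); @param b hazard-rate shape (ignored for half-normal).
#' @param adjustment `"none"`, `"cosine"` or `"polynomial"`.
#' @param adj_coefs numeric adjustment coefficients (length = order).
#' @param w truncation distance (m); required when adjustments are used.
#' @return g(d) values; g(0) = 1 exactly.
#' @export
detection_g <- function(d, key = c("hazard_rate", "half_normal"), sigma, b = NULL,
                        adjustment = "none", adj_coefs = numeric(0), w = NULL) {
  key <- match.arg(key)
  gk <- if (key == "hazard_rate") {
    if (is.null(b)) stop_config("hazard_rate key needs shape b")
    hazard_rate_g(d, sigma, b)
  } else {
    half_normal_g(d, sigma)
  }
  if (adjustment == "none" || !length(adj_coefs)) return(gk)
  if (is.null(w)) stop_config("adjustments need the truncation distance w")
  s <- .adjustment_series(d, w, adjustment, length(adj_coefs))
  s0 <- .adjustment_series(0, w, adjustment, length(adj_coefs))
  num <- 1 + drop(s %*% adj_coefs)
  den <- 1 + drop(s0 %*% adj_coefs)
  pmax(gk * num / den, 0)
}

#' Average detection probability within the truncated strip
#'
#' p = (1/w) * integral_0^w g(x) dx, by adaptive quadrature. For covariate
#' (MCDS) models call once per stratum scale.
#'
#' @inheritParams detection_g
#' @param w truncation distance (m).
#' @return probability in (0, 1]; vectorized over `sigma`.
#' @export
#' @examples
#' average_p(sigma = 30, key = "half_normal", w = 100)
average_p <- function(sigma, key = c("hazard_rate", "half_normal"), b = NULL, w,
                      adjustment = "none", adj_coefs = numeric(0)) {
  key <- match.arg(key)
  vapply(sigma, function(s) {
    stats::integrate(detection_g, 0, w,
      key = key, sigma = s, b = b,
      adjustment = adjustment, adj_coefs = adj_coefs, w = w,
      rel.tol = 1e-10, subdivisions = 400L
    )$value / w
  }, numeric(1))
}

#' Strip width implied by a truncation distance
#'
#' @param truncation_m truncation distance (m).
#' @param sides number of survey sides (2 for both sides of the vessel).
#' @return strip width in metres.
#' @export
#' @examples
#' strip_width(100) # 200
strip_width <- function(truncation_m, sides = 2) truncation_m * sides

#' Smearing configuration
#'
#' Uniform smearing over the angle-distance sector (theta - phi, theta + phi)
#' x (r (1 - s), r (1 + s)) that a heaped measurement plausibly came from.
#' `s_prop` is a proportion of the recorded radial distance.
#'
#' @param phi_deg smear half-angle, degrees (default 5).
#' @param s_prop proportional distance half-width in [0, 1) (default 0.2).
#' @param mode `"fractional"`: deterministically spread each sighting's weight
#'   over distance bins by numerical integration; `"draw"`: one random
#'   (angle, radius) realisation per individual.
#' @param seed RNG seed for `mode = "draw"`.
#' @export
smear_config <- function(phi_deg = 5, s_prop = 0.2,
                         mode = c("fractional", "draw"), seed = 1L) {
  mode <- match.arg(mode)
  if (phi_deg < 0) stop_config("phi_deg must be >= 0")
  if (s_prop < 0 || s_prop >= 1) stop_config("s_prop must be in [0, 1)")
  structure(list(phi_deg = phi_deg, s_prop = s_prop, mode = mode, seed = seed),
            class = "smear_config")
}

#' Distance bin scheme
#'
#' @param edges_m strictly increasing bin edges in metres, starting at 0; the
#'   last edge is the truncation distance.
#' @export
bin_scheme <- function(edges_m = c(0, 5, 10, 20, 30, 40, 50, 100)) {
  if (any(diff(edges_m) <= 0) || edges_m[1] != 0) {
    stop_config("edges_m must start at 0 and be strictly increasing")
  }
  structure(list(edges_m = edges_m, truncation_m = edges_m[length(edges_m)]),
            class = "bin_scheme")
}

#' Smear one heaped sighting into distance-bin weights
#'
#' Treats (angle, radius) as uniform on the smear sector, maps the induced
#' perpendicular distances onto the bin scheme on a fixed quadrature grid, and
#' returns fractional bin weights summing (with the truncated remainder) to
#' `n_individuals`. Mass falling beyond the truncation edge is discarded and
#' reported, never renormalized.
#'
#' @param radial_m,angle_deg recorded (heaped) measurements.
#' @param n_individuals group size (>= 1).
#' @param cfg a [smear_config()]; @param bins a [bin_scheme()].
#' @param grid_n quadrature grid points per sector axis (default 41).
#' @return list with `weights` (per retained bin) and `truncated` mass.
#' @export
smear_to_bins <- function(radial_m, angle_deg, n_individuals = 1,
                          cfg = smear_config(), bins = bin_scheme(),
                          grid_n = 41L) {
  edges <- bins$edges_m
  nb <- length(edges) - 1L
  a_lo <- max(0, angle_deg - cfg$phi_deg)      # sector clipped at 0 degrees
  a_hi <- min(180, angle_deg + cfg$phi_deg)
  r_lo <- max(0, radial_m * (1 - cfg$s_prop))
  r_hi <- radial_m * (1 + cfg$s_prop)

  if (cfg$mode == "draw") {
    set.seed(cfg$seed)
    th <- stats::runif(n_individuals, a_lo, a_hi)
    rr <- stats::runif(n_individuals, r_lo, r_hi)
    d <- rr * sin(th * DEG2RAD)
  } else {
    th <- if (a_hi > a_lo) a_lo + (seq_len(grid_n) - 0.5) / grid_n * (a_hi - a_lo) else angle_deg
    rr <- if (r_hi > r_lo) r_lo + (seq_len(grid_n) - 0.5) / grid_n * (r_hi - r_lo) else radial_m
    d <- as.vector(outer(rr, sin(th * DEG2RAD)))
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  w_unit <- n_individuals / length(d)
  inside <- idx >= 1L & idx <= nb
  weights <- numeric(nb)
  if (any(inside)) {
    tab <- tabulate(idx[inside], nbins = nb)
    weights <- tab * w_unit
  }
  list(weights = weights, truncated = sum(!inside) * w_unit)
}

#' Bin a sighting table for detection-function fitting
#'
#' Applies smearing sighting-by-sighting and attaches the detection covariates
#' of the parent transect. Truncation at the last bin edge is applied here:
#' smeared mass beyond it is dropped and totalled in the `truncated`
#' attribute.
#'
#' @param sightings sighting table (`transect_id`, `radial_m`, `angle_deg`,
#'   `n_individuals`).
#' @param transects parent transect table (for `beaufort`, `glare`,
#'   `speed_kmh`).
#' @param cfg a [smear_config()]; @param bins a [bin_scheme()].
#' @return object of class `binned_sightings`: list with `W` (sightings x bins
#'   weight matrix), `covars` (per-sighting covariate data.frame), `bins`,
#'   and attributes `truncated` (discarded mass) and `total` (individuals in).
#' @export
bin_sightings <- function(sightings, transects, cfg = smear_config(),
                          bins = bin_scheme()) {
  m <- match(sightings$transect_id, transects$transect_id)
  if (anyNA(m)) stop_config("sightings reference unknown transect_id(s)")
  nb <- length(bins$edges_m) - 1L
  n <- nrow(sightings)
  W <- matrix(0, n, nb)
  trunc_mass <- 0
  for (i in seq_len(n)) {
    sw <- smear_to_bins(sightings$radial_m[i], sightings$angle_deg[i],
                        sightings$n_individuals[i], cfg, bins)
    W[i, ] <- sw$weights
    trunc_mass <- trunc_mass + sw$truncated
  }
  covars <- data.frame(
    beaufort = factor(transects$beaufort[m]),
    glare = factor(transects$glare[m]),
    speed_kmh = transects$speed_kmh[m],
    stringsAsFactors = FALSE
  )
  keep <- rowSums(W) > 0
  structure(
    list(W = W[keep, , drop = FALSE], covars = covars[keep, , drop = FALSE],
         bins = bins),
    truncated = trunc_mass, total = sum(sightings$n_individuals),
    class = "binned_sightings"
  )
}

## per-bin integrals of g for a vector of bin edges, 24-node Gauss-Legendre
.bin_integrals <- function(edges, key, sigma, b, adjustment, adj_coefs) {
  gl <- gauss_legendre(24L)
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (j in seq_len(nb)) {
    a <- edges[j]; bb <- edges[j + 1]
    x <- a + gl$nodes * (bb - a)
    out[j] <- sum(gl$weights * detection_g(x, key, sigma, b, adjustment,
                                           adj_coefs, edges[length(edges)])) * (bb - a)
  }
  out
}

## negative binned conditional-multinomial log-likelihood for one candidate
.det_nll <- function(par, cand, W, Xs, edges, stratum_of) {
  nb <- ncol(W)
  i <- 1L
  beta <- par[seq_len(ncol(Xs))]; i <- i + ncol(Xs)
  b <- NULL
  if (cand$key == "hazard_rate") { b <- exp(par[i]); i <- i + 1L }
  adj <- if (cand$adjustment != "none") par[i - 1L + seq_len(cand$adj_order)] else numeric(0)
  sigma_s <- exp(drop(Xs %*% beta))
  if (any(!is.finite(sigma_s)) || any(sigma_s <= 0)) return(1e10)
  ll <- 0
  for (s in seq_len(nrow(Xs))) {
    pj <- .bin_integrals(edges, cand$key, sigma_s[s], b, cand$adjustment, adj)
    if (any(pj <= 0) || !all(is.finite(pj))) return(1e10)
    pj <- pj / sum(pj)
    rows <- which(stratum_of == s)
    ll <- ll + sum(W[rows, , drop = FALSE] %*% log(pj))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Default candidate set for detection-function selection
#'
#' Hazard-rate and half-normal keys, null/cosine/polynomial adjustments up to
#' order 2, with and without Beaufort sea state as a scale covariate.
#' @return list of candidate descriptions for [fit_detection()].
#' @export
default_detection_candidates <- function() {
  out <- list()
  for (key in c("hazard_rate", "half_normal")) {
    for (cov in list(character(0), "beaufort")) {
      out[[length(out) + 1L]] <- list(key = key, adjustment = "none",
                                      adj_order = 0L, covars = cov)
    }
    for (adj in c("cosine", "polynomial")) {
      for (ord in 1:2) {
        out[[length(out) + 1L]] <- list(key = key, adjustment = adj,
                                        adj_order = ord, covars = character(0))
      }
    }
  }
  out
}

#' Fit detection functions to binned distance data and select by AIC
#'
#' Maximizes the binned conditional-on-detection multinomial likelihood: for
#' each covariate stratum the probability of a detection falling in bin j is
#' proportional to the integral of g over that bin. Covariates act on the
#' scale, log sigma = X beta, with the hazard-rate shape shared across strata.
#' Fractional (smeared) weights are supported. Each candidate is fitted by
#' quasi-Newton; candidates that fail to converge or whose fitted g is not
#' monotone non-increasing are discarded; the lowest-AIC survivor is returned
#' (ties broken toward fewer parameters).
#'
#' @param binned a [bin_sightings()] result.
#' @param candidates list of candidates (see
#'   [default_detection_candidates()]).
#' @param effort optional per-stratum effort weights for the overall p (by
#'   default detections-weighted).
#' @return object of class `detection_model`.
#' @export
fit_detection <- function(binned, candidates = default_detection_candidates(),
                          effort = NULL) {
  W <- binned$W
  edges <- binned$bins$edges_m
  if (sum(colSums(W) > 0) < 2) stop_config("need >= 2 non-empty distance bins")
  fits <- list()
  for (cand in candidates) {
    f <- tryCatch(.fit_one_candidate(cand, W, binned$covars, edges),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("candidate %s/%s(order %d)/%s failed; skipped",
                      cand$key, cand$adjustment, cand$adj_order,
                      paste(cand$covars, collapse = "+")), call. = FALSE)
      next
    }
    fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop_config("all detection-function candidates failed")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  best <- order(round(aics, 6), ks)[1]
  model <- fits[[best]]
  model$all_candidates <- data.frame(
    key = vapply(fits, function(f) f$key, character(1)),
    adjustment = vapply(fits, function(f) f$adjustment, character(1)),
    covars = vapply(fits, function(f) paste(f$covars, collapse = "+"), character(1)),
    k = ks, aic = aics
  )
  model$bins <- binned$bins
  class(model) <- "detection_model"
  model
}

.fit_one_candidate <- function(cand, W, covars, edges) {
  w <- edges[length(edges)]
  ## stratum design matrix on unique covariate combinations
  if (length(cand$covars)) {
    cv <- covars[, cand$covars, drop = FALSE]
    key_str <- do.call(paste, c(cv, sep = "\r"))
    ustr <- sort(unique(key_str))
    stratum_of <- match(key_str, ustr)
    urows <- cv[match(ustr, key_str), , drop = FALSE]
    Xs <- stats::model.matrix(stats::reformulate(cand$covars), data = urows)
  } else {
    stratum_of <- rep(1L, nrow(W))
    Xs <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
    urows <- NULL
  }
  ## starting values from the weighted mean perpendicular distance
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dbar <- sum(colSums(W) * mids) / sum(W)
  par0 <- c(log(max(dbar, 1)), rep(0, ncol(Xs) - 1))
  if (cand$key == "hazard_rate") par0 <- c(par0, log(2.5))
  if (cand$adjustment != "none") par0 <- c(par0, rep(0, cand$adj_order))
  opt <- stats::optim(par0, .det_nll, cand = cand, W = W, Xs = Xs,
                      edges = edges, stratum_of = stratum_of,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  if (opt$value >= 1e9) stop("non-convergence")
  i <- 1L
  beta <- opt$par[seq_len(ncol(Xs))]; i <- i + ncol(Xs)
  b <- NULL
  if (cand$key == "hazard_rate") { b <- exp(opt$par[i]); i <- i + 1L }
  adj <- if (cand$adjustment != "none") opt$par[i - 1L + seq_len(cand$adj_order)] else numeric(0)
  sigma_s <- exp(drop(Xs %*% beta))
  ## monotonicity screen on every stratum's fitted curve
  dd <- seq(0, w, length.out = 201)
  for (s in seq_along(sigma_s)) {
    gs <- detection_g(dd, cand$key, sigma_s[s], b, cand$adjustment, adj, w)
    if (any(diff(gs) > 1e-6)) stop("non-monotone fit")
  }
  k <- length(opt$par)
  p_s <- vapply(sigma_s, function(s)
    average_p(s, cand$key, b, w, cand$adjustment, adj), numeric(1))
  n_s <- vapply(seq_along(sigma_s), function(s)
    sum(W[stratum_of == s, , drop = FALSE]), numeric(1))
  names(p_s) <- if (!is.null(urows)) do.call(paste, c(urows, sep = ":")) else "all"
  list(
    key = cand$key, adjustment = cand$adjustment, adj_coefs = adj,
    covars = cand$covars, scale_coefs = stats::setNames(beta, colnames(Xs)),
    shape_b = b, sigma_by_stratum = stats::setNames(sigma_s, names(p_s)),
    p_by_stratum = p_s, p_overall = sum(p_s * n_s) / sum(n_s),
    loglik = -opt$value, k = k, aic = 2 * k + 2 * opt$value,
    truncation_m = w, stratum_levels = urows, n_by_stratum = n_s
  )
}

#' Predict per-transect detection probability from a fitted model
#'
#' @param model a [fit_detection()] result.
#' @param transects transect table supplying the model's covariates.
#' @return numeric vector of average detection probabilities, one per transect.
#' @export
predict_p <- function(model, transects) {
  if (!length(model$covars)) {
    return(rep(model$p_overall, nrow(transects)))
  }
  cv <- data.frame(
    beaufort = factor(transects$beaufort,
                      levels = levels(model$stratum_levels$beaufort %||%
                                        factor(transects$beaufort))),
    glare = factor(transects$glare),
    speed_kmh = transects$speed_kmh
  )[, model$covars, drop = FALSE]
  Xn <- stats::model.matrix(stats::reformulate(model$covars), data = cv)
  Xn <- Xn[, names(model$scale_coefs), drop = FALSE]
  sig <- exp(drop(Xn %*% model$scale_coefs))
  usig <- unique(sig)
  pu <- vapply(usig, function(s)
    average_p(s, model$key, model$shape_b, model$truncation_m,
              model$adjustment, model$adj_coefs), numeric(1))
  pu[match(sig, usig)]
}

#' Chi-square goodness of fit for a binned detection model
#'
#' Pearson chi-square of observed vs model-expected bin counts, pooled over
#' covariate strata; df = bins - n_params - 1.
#'
#' @param model a [fit_detection()] result.
#' @param binned the [bin_sightings()] data it was fitted to.
#' @return list with `chi2`, `df`, `p`, and the observed/expected tables.
#' @export
gof_chisq <- function(model, binned) {
  W <- binned$W
  edges <- binned$bins$edges_m
  nb <- ncol(W)
  if (nb <= model$k + 1) stop_config("too few bins for a goodness-of-fit test")
  if (length(model$covars)) {
    cv <- binned$covars[, model$covars, drop = FALSE]
    key_str <- do.call(paste, c(cv, sep = "\r"))
    ustr <- do.call(paste, c(model$stratum_levels, sep = "\r"))
    stratum_of <- match(key_str, ustr)
  } else stratum_of <- rep(1L, nrow(W))
  expected <- numeric(nb)
  for (s in seq_along(model$sigma_by_stratum)) {
    pj <- .bin_integrals(edges, model$key, model$sigma_by_stratum[s],
                         model$shape_b, model$adjustment, model$adj_coefs)
    pj <- pj / sum(pj)
    ns <- sum(W[stratum_of == s, , drop = FALSE])
    expected <- expected + ns * pj
  }
  observed <- colSums(W)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- nb - model$k - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("Detection function: %s key, %s adjustment%s\n", x$key,
              x$adjustment,
              if (length(x$covars)) paste0(", covariates: ",
                                           paste(x$covars, collapse = "+")) else ""))
  if (!is.null(x$shape_b)) cat(sprintf("  shape b = %.3f\n", x$shape_b))
  cat(sprintf("  truncation %g m, AIC %.2f, average p = %.3f\n",
              x$truncation_m, x$aic, x$p_overall))
  if (length(x$p_by_stratum) > 1) {
    cat("  p by stratum:\n")
    print(round(x$p_by_stratum, 3))
  }
  invisible(x)
}
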