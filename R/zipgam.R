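#' Zero-inflated Poisson GAM standardization of sighting counts
#'
#' Transect counts are modelled as a zero-inflated Poisson with a log
#' effective-area offset: lambda_i = exp(eta_i + log A_i) with
#' eta = X beta + f(dcoast) + Z u, where f is a penalized cubic regression
#' spline, u are ridge-penalized i.i.d. observer effects, and the probability
#' of a structural zero is 1 - logistic(gamma0 + gamma1 * eta) (a one-stage
#' formulation tying zero inflation to the same linear predictor; a
#' constant-probability fallback and a pure Poisson variant are provided).
#' Parameters are estimated by penalized likelihood maximization with an
#' analytic gradient; smoothing/ridge parameters are chosen on an outer grid
#' minimizing conditional AIC (2 edf - 2 loglik). Annual relative-abundance
#' indices come from standardized prediction over the pooled covariate
#' distribution, in individuals per 0.1 km^2 of effective area.
#'
#' @name zipgam
NULL

#' Effective area surveyed by a transect
#'
#' transect length x strip width x sighting probability, the exposure offset
#' of the count model.
#'
#' @param length_km transect length (km), > 0.
#' @param strip_width_km two-sided strip width (km), > 0.
#' @param p average detection probability in (0, 1].
#' @return effective area in km^2.
#' @export
#' @examples
#' effective_area(3.82, 0.2, 0.148)
effective_area <- function(length_km, strip_width_km, p) {
  if (any(length_km <= 0) || any(strip_width_km <= 0) || any(p <= 0)) {
    stop_config("effective_area needs strictly positive inputs")
  }
  length_km * strip_width_km * p
}

#' Zero-inflated Poisson log-likelihood
#'
#' l = sum_{y=0} log(pi + (1-pi) e^-lambda)
#'   + sum_{y>0} (log(1-pi) - lambda + y log lambda - log y!).
#' Reduces exactly to the Poisson log-likelihood at pi = 0.
#'
#' @param y non-negative integer counts.
#' @param lambda Poisson means (recycled).
#' @param pi structural-zero probabilities in [0, 1] (recycled).
#' @return total log-likelihood.
#' @export
zip_loglik <- function(y, lambda, pi = 0) {
  n <- max(length(y), length(lambda), length(pi))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n); pi <- rep_len(pi, n)
  ll <- numeric(n)
  z <- y == 0
  ll[z] <- log(pi[z] + (1 - pi[z]) * exp(-lambda[z]))
  ll[!z] <- log(1 - pi[!z]) - lambda[!z] + y[!z] * log(lambda[!z]) - lgamma(y[!z] + 1)
  sum(ll)
}

#' Relative change in percent
#' @param a baseline value; @param b new value.
#' @return 100 * (b - a) / a.
#' @export
#' @examples
#' percent_change(0.0689, 0.0229) # about -67
percent_change <- function(a, b) 100 * (b - a) / a

#' Count-model specification
#'
#' @param terms candidate model terms among `"year"`, `"beaufort"`,
#'   `"time_group"`, `"sst"`, `"s(dcoast_km)"`, `"observer"`, and optional
#'   linear extras `"speed"`, `"depth"`, `"slope"`, `"d500"`, `"d1000"`,
#'   `"sshd"`, `"lat"`, `"lon"`, `"npp"`.
#' @param k basis size of the distance-to-coast smooth (>= 4).
#' @param collinearity_r pairwise |Pearson r| above which the later-listed of
#'   two numeric candidates is dropped before fitting.
#' @param zi zero-inflation formulation: `"linked"` (structural-zero
#'   probability 1 - logistic(gamma0 + gamma1 eta)), `"constant"`
#'   (gamma1 = 0) or `"none"` (pure Poisson).
#' @export
model_spec <- function(terms = c("year", "beaufort", "time_group", "sst",
                                 "s(dcoast_km)", "observer"),
                       k = 8L, collinearity_r = 0.7,
                       zi = c("linked", "constant", "none")) {
  zi <- match.arg(zi)
  if (k < 4) stop_config("smooth basis size k must be >= 4")
  structure(list(terms = terms, k = as.integer(k),
                 collinearity_r = collinearity_r, zi = zi),
            class = "model_spec")
}

.linear_term_cols <- c(
  speed = "speed_kmh", depth = "depth_m", slope = "slope_deg",
  d500 = "d500_km", d1000 = "d1000_km", sshd = "sshd_m",
  lat = "lat_start", lon = "lon_start", npp = "npp_mgc_m2_d", sst = "sst_c"
)

#' Pairwise collinearity screen
#'
#' Drops the later-listed member of any pair of numeric candidate covariates
#' whose absolute Pearson correlation exceeds the threshold.
#'
#' @param data transect table.
#' @param vars candidate term names (numeric candidates only are screened).
#' @param threshold |r| cutoff (default 0.7).
#' @return list with `keep` (retained term names) and `dropped`
#'   (data.frame of removals with the offending correlation).
#' @export
collinearity_screen <- function(data, vars, threshold = 0.7) {
  num <- vars[vars %in% names(.linear_term_cols)]
  dropped <- data.frame(term = character(), against = character(), r = numeric())
  keep <- vars
  if (length(num) >= 2) {
    cols <- .linear_term_cols[num]
    cm <- stats::cor(data[, cols, drop = FALSE], use = "complete.obs")
    dimnames(cm) <- list(num, num)
    for (j in seq_along(num)[-1]) {
      if (!(num[j] %in% keep)) next
      earlier <- num[seq_len(j - 1)]
      earlier <- earlier[earlier %in% keep]
      if (!length(earlier)) next
      r <- cm[num[j], earlier]
      if (any(abs(r) > threshold)) {
        hit <- earlier[which.max(abs(r))]
        dropped <- rbind(dropped, data.frame(term = num[j], against = hit,
                                             r = cm[num[j], hit]))
        keep <- setdiff(keep, num[j])
      }
    }
  }
  list(keep = keep, dropped = dropped)
}

.make_time_group <- function(time_block) {
  factor(ifelse(time_block <= 1100, "morning",
                ifelse(time_block <= 1500, "midday", "afternoon")),
         levels = c("morning", "midday", "afternoon"))
}

## Build the combined design matrix and penalty blocks for a term set.
## `info` (levels, centres, smooth constructor) is created on first build and
## reused for prediction so columns always align.
.build_design <- function(data, terms, k, info = NULL) {
  first <- is.null(info)
  if (first) info <- list(k = k)
  mats <- list(`(Intercept)` = matrix(1, nrow(data), 1,
                                      dimnames = list(NULL, "(Intercept)")))
  pens <- list()
  tcols <- list(`(Intercept)` = 1L)

  add_factor <- function(nm, values) {
    lev_key <- paste0(nm, "_levels")
    if (first) info[[lev_key]] <<- levels(factor(values))
    f <- factor(values, levels = info[[lev_key]])
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(nm, info[[lev_key]][-1])
    mats[[nm]] <<- mm
  }

  for (tm in terms) {
    if (tm == "year") add_factor("year", data$year)
    else if (tm == "beaufort") add_factor("beaufort", data$beaufort)
    else if (tm == "time_group") add_factor("time_group", .make_time_group(data$time_block))
    else if (tm == "observer") {
      if (first) info$observer_levels <- levels(factor(data$observer_id))
      f <- factor(data$observer_id, levels = info$observer_levels)
      mm <- stats::model.matrix(~ 0 + f)
      colnames(mm) <- paste0("obs_", info$observer_levels)
      mats[[tm]] <- mm
      pens[[tm]] <- list(term = tm, S = diag(ncol(mm)), kind = "ridge")
    } else if (tm == "s(dcoast_km)") {
      if (first) {
        info$sm <- mgcv::smoothCon(mgcv::s(dcoast_km, bs = "cr", k = k),
                                   data = data, absorb.cons = TRUE)[[1]]
        mm <- info$sm$X
      } else {
        mm <- mgcv::PredictMat(info$sm, data)
      }
      colnames(mm) <- paste0("s_dcoast_", seq_len(ncol(mm)))
      mats[[tm]] <- mm
      pens[[tm]] <- list(term = tm, S = info$sm$S[[1]], kind = "smooth")
    } else if (tm %in% names(.linear_term_cols)) {
      col <- .linear_term_cols[[tm]]
      cen_key <- paste0(tm, "_centre")
      if (first) info[[cen_key]] <- mean(data[[col]], na.rm = TRUE)
      mm <- matrix(data[[col]] - info[[cen_key]], ncol = 1,
                   dimnames = list(NULL, tm))
      mats[[tm]] <- mm
    } else stop_config("unknown model term '%s'", tm)
  }

  C <- do.call(cbind, mats)
  ofs <- 0L
  for (nm in names(mats)) {
    tcols[[nm]] <- ofs + seq_len(ncol(mats[[nm]]))
    ofs <- ofs + ncol(mats[[nm]])
  }
  for (nm in names(pens)) pens[[nm]]$cols <- tcols[[nm]]
  list(C = C, pens = pens, term_cols = tcols, info = info)
}

## The slope of the zero-inflation link is kept in (0, GAMMA1_MAX) through a
## logistic reparameterization: gamma1 = GAMMA1_MAX * plogis(psi). Unbounded,
## the slope admits a degenerate separation-type optimum; positivity encodes
## zero inflation decreasing with density.
GAMMA1_MAX <- 5

## penalized negative log-likelihood and gradient for the ZIP-GAM
.zip_obj <- function(par, y, C, offset, P, zi) {
  p <- ncol(C)
  beta <- par[seq_len(p)]
  eta <- drop(C %*% beta)
  etao <- pmin(eta + offset, 30)
  mu <- exp(etao)
  z <- y == 0
  if (zi == "none") {
    ll <- sum(-mu + y * etao - lgamma(y + 1))
  } else {
    g0 <- par[p + 1L]
    g1 <- if (zi == "linked") GAMMA1_MAX * stats::plogis(par[p + 2L]) else 0
    q <- g0 + g1 * eta
    p1 <- stats::plogis(q)
    L0 <- pmax(1 - p1[z] * (1 - exp(-mu[z])), 1e-300)
    ll <- sum(log(L0)) +
      sum(stats::plogis(q[!z], log.p = TRUE) - mu[!z] + y[!z] * etao[!z] - lgamma(y[!z] + 1))
  }
  pen <- 0.5 * drop(crossprod(beta, P %*% beta))
  -(ll - pen)
}

.zip_grad <- function(par, y, C, offset, P, zi) {
  p <- ncol(C)
  beta <- par[seq_len(p)]
  eta <- drop(C %*% beta)
  etao <- pmin(eta + offset, 30)
  mu <- exp(etao)
  z <- y == 0
  if (zi == "none") {
    deta <- y - mu
    gb <- drop(crossprod(C, deta)) - drop(P %*% beta)
    return(-gb)
  }
  g0 <- par[p + 1L]
  g1 <- if (zi == "linked") GAMMA1_MAX * stats::plogis(par[p + 2L]) else 0
  q <- g0 + g1 * eta
  p1 <- stats::plogis(q)
  dldeta <- numeric(length(y))
  dldq <- numeric(length(y))
  em <- exp(-mu[z])
  L0 <- pmax(1 - p1[z] * (1 - em), 1e-300)
  dldeta[z] <- -p1[z] * em * mu[z] / L0
  dldq[z] <- -p1[z] * (1 - p1[z]) * (1 - em) / L0
  dldeta[!z] <- y[!z] - mu[!z]
  dldq[!z] <- 1 - p1[!z]
  deta <- dldeta + g1 * dldq
  gb <- drop(crossprod(C, deta)) - drop(P %*% beta)
  gr <- c(gb, sum(dldq))
  if (zi == "linked") {
    ps <- stats::plogis(par[p + 2L])
    gr <- c(gr, sum(eta * dldq) * GAMMA1_MAX * ps * (1 - ps))
  }
  -gr
}

.assemble_penalty <- function(p, pens, lambda_s, lambda_u) {
  P <- matrix(0, p, p)
  for (pe in pens) {
    lam <- if (pe$kind == "smooth") lambda_s else lambda_u
    P[pe$cols, pe$cols] <- P[pe$cols, pe$cols] + lam * pe$S
  }
  P
}

## one inner fit at fixed penalties; returns everything needed for cAIC.
## Objective and gradient share one cached evaluation per parameter vector
## (BFGS asks for both at the same point).
.zip_fit_inner <- function(y, C, offset, P, zi, start = NULL) {
  p <- ncol(C)
  ng <- switch(zi, none = 0L, constant = 1L, linked = 2L)
  if (is.null(start)) {
    b0 <- log(max(sum(y), 0.5) / sum(exp(offset)))
    start <- c(b0, rep(0, p - 1), c(1, 0)[seq_len(ng)])
  }
  z <- y == 0
  nz <- !z
  ypos <- y[nz]
  lgy <- sum(lgamma(ypos + 1))
  cache <- new.env(parent = emptyenv())
  evalpt <- function(par) {
    if (identical(cache$par, par)) return(cache$val)
    beta <- par[seq_len(p)]
    eta <- drop(C %*% beta)
    etao <- pmin(eta + offset, 30)
    mu <- exp(etao)
    Pb <- drop(P %*% beta)
    if (zi == "none") {
      ll <- sum(ypos * etao[nz]) - sum(mu) - lgy
      deta <- y - mu
      ngr <- -(drop(crossprod(C, deta)) - Pb)
    } else {
      g0 <- par[p + 1L]
      psl <- if (zi == "linked") 1 / (1 + exp(-par[p + 2L])) else 0
      g1 <- GAMMA1_MAX * psl
      q <- g0 + g1 * eta
      p1 <- 1 / (1 + exp(-q))
      em <- exp(-mu[z])
      L0 <- pmax(1 - p1[z] * (1 - em), 1e-300)
      qn <- q[nz]
      lp1 <- ifelse(qn < 0, qn - log1p(exp(qn)), -log1p(exp(-qn)))
      ll <- sum(log(L0)) +
        sum(lp1 - mu[nz] + ypos * etao[nz]) - lgy
      dldeta <- dldq <- numeric(length(y))
      dldeta[z] <- -p1[z] * em * mu[z] / L0
      dldq[z] <- -p1[z] * (1 - p1[z]) * (1 - em) / L0
      dldeta[nz] <- ypos - mu[nz]
      dldq[nz] <- 1 - p1[nz]
      deta <- dldeta + g1 * dldq
      gr <- c(drop(crossprod(C, deta)) - Pb, sum(dldq))
      if (zi == "linked") {
        gr <- c(gr, sum(eta * dldq) * GAMMA1_MAX * psl * (1 - psl))
      }
      ngr <- -gr
    }
    nll <- -(ll - 0.5 * sum(beta * Pb))
    cache$par <- par
    cache$val <- list(nll = nll, ngr = ngr)
    cache$val
  }
  opt <- stats::optim(start, function(par) evalpt(par)$nll,
                      function(par) evalpt(par)$ngr,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-11))
  par <- opt$par
  beta <- par[seq_len(p)]
  gamma <- if (ng) par[p + seq_len(ng)] else numeric(0)
  if (zi == "linked") gamma[2] <- GAMMA1_MAX * stats::plogis(gamma[2])
  eta <- drop(C %*% beta)
  ll <- -.zip_obj(par, y, C, offset, matrix(0, p, p), zi)

  ## per-observation curvature of the log-likelihood in eta (gamma held
  ## fixed), by central differencing of the analytic eta-score
  score_eta <- function(e) {
    etao <- pmin(e + offset, 30); mu <- exp(etao)
    z <- y == 0
    if (zi == "none") return(y - mu)
    g0 <- gamma[1]; g1 <- if (zi == "linked") gamma[2] else 0
    q <- g0 + g1 * e
    p1 <- stats::plogis(q)
    out <- numeric(length(y))
    em <- exp(-mu[z])
    L0 <- pmax(1 - p1[z] * (1 - em), 1e-300)
    out[z] <- -p1[z] * em * mu[z] / L0 + g1 * (-p1[z] * (1 - p1[z]) * (1 - em) / L0)
    out[!z] <- (y[!z] - mu[!z]) + g1 * (1 - p1[!z])
    out
  }
  eps <- 1e-4
  w <- pmax(-(score_eta(eta + eps) - score_eta(eta - eps)) / (2 * eps), 0)
  H <- crossprod(C * sqrt(w))
  Hp <- H + P + diag(1e-8 * max(diag(H), 1), p)
  edf <- sum(diag(solve(Hp, H))) + ng
  list(par = par, beta = beta, gamma = gamma, eta = eta, loglik = ll,
       edf = edf, caic = 2 * edf - 2 * ll, H = H, Hp = Hp,
       convergence = opt$convergence, w = w)
}

#' Fit the zero-inflated Poisson GAM
#'
#' @param data QC-filtered transect table (needs `count`, the covariates named
#'   by the spec's terms, and `observer_id` when the observer term is used).
#' @param spec a [model_spec()].
#' @param offset_log log effective area per transect (km^2), same length as
#'   `data` rows.
#' @param lambda_s,lambda_u smoothing and observer-ridge penalties; `NULL`
#'   (default) selects each on a log-spaced grid by conditional AIC.
#' @param screen apply the spec's collinearity screen to the numeric
#'   candidate terms before fitting (default TRUE).
#' @param start optional warm-start parameter vector.
#' @return object of class `zipgam_fit`.
#' @export
fit_zipgam <- function(data, spec = model_spec(), offset_log,
                       lambda_s = NULL, lambda_u = NULL, screen = TRUE,
                       start = NULL) {
  if (length(offset_log) != nrow(data)) stop_config("offset_log length mismatch")
  if (any(!is.finite(offset_log))) stop_config("offset must be finite")
  y <- data$count
  if (all(y == 0)) stop_config("all-zero response: nothing to fit")
  terms <- spec$terms
  screen_info <- NULL
  if (screen) {
    sc <- collinearity_screen(data, terms, spec$collinearity_r)
    terms <- sc$keep
    screen_info <- sc$dropped
  }
  des <- .build_design(data, terms, spec$k, info = NULL)
  p <- ncol(des$C)
  has_smooth <- any(vapply(des$pens, function(z) z$kind == "smooth", logical(1)))
  has_ridge <- any(vapply(des$pens, function(z) z$kind == "ridge", logical(1)))

  ls_grid <- if (!is.null(lambda_s)) lambda_s else if (has_smooth) 10^seq(-2, 4, length.out = 7) else 1
  lu_grid <- if (!is.null(lambda_u)) lambda_u else if (has_ridge) 10^seq(-1, 3, length.out = 5) else 1

  ng <- switch(spec$zi, none = 0L, constant = 1L, linked = 2L)
  if (!is.null(start) && length(start) != p + ng) start <- NULL
  best <- NULL
  warm <- start
  lu_mid <- lu_grid[ceiling(length(lu_grid) / 2)]
  for (ls in ls_grid) {
    P <- .assemble_penalty(p, des$pens, ls, lu_mid)
    f <- .zip_fit_inner(y, des$C, offset_log, P, spec$zi, start = warm)
    warm <- f$par
    if (is.null(best) || f$caic < best$caic) best <- c(f, list(lambda_s = ls, lambda_u = lu_mid))
  }
  if (length(lu_grid) > 1) {
    warm <- best$par
    for (lu in lu_grid) {
      if (lu == best$lambda_u) next
      P <- .assemble_penalty(p, des$pens, best$lambda_s, lu)
      f <- .zip_fit_inner(y, des$C, offset_log, P, spec$zi, start = warm)
      if (f$caic < best$caic) best <- c(f, list(lambda_s = best$lambda_s, lambda_u = lu))
    }
  }

  eta <- best$eta
  g1 <- if (spec$zi == "linked") best$gamma[2] else 0
  p1 <- if (spec$zi == "none") rep(1, length(eta)) else {
    stats::plogis(best$gamma[1] + g1 * eta)
  }
  dev <- .zip_deviance(y, best$loglik)
  obs_cols <- des$term_cols[["observer"]]

  structure(
    list(
      coefficients = stats::setNames(best$beta, colnames(des$C)),
      gamma = best$gamma, zi = spec$zi,
      eta = eta, offset_log = offset_log, fitted_p1 = p1,
      lambda_s = best$lambda_s, lambda_u = best$lambda_u,
      edf = best$edf, loglik = best$loglik, caic = best$caic,
      deviance = dev,
      observer_sd_hat = if (!is.null(obs_cols)) stats::sd(best$beta[obs_cols]) else NA_real_,
      terms = terms, spec = spec, design_info = des$info,
      term_cols = des$term_cols, pens = des$pens, Hp = best$Hp,
      screen_dropped = screen_info,
      data = data, y = y,
      convergence = best$convergence, par = best$par
    ),
    class = "zipgam_fit"
  )
}

.zip_deviance <- function(y, loglik) {
  pos <- y > 0
  ll_sat <- sum(y[pos] * log(y[pos]) - y[pos] - lgamma(y[pos] + 1))
  2 * (ll_sat - loglik)
}

#' Fraction of null deviance explained
#'
#' 1 - deviance(fit) / deviance(null), where the null model keeps only the
#' intercept, the offset and the zero-inflation parameters.
#'
#' @param fit a [fit_zipgam()] result.
#' @param null_fit optional pre-computed null fit (same zi formulation).
#' @return fraction in [0, 1].
#' @export
deviance_explained <- function(fit, null_fit = NULL) {
  if (is.null(null_fit)) {
    null_fit <- fit_zipgam(fit$data,
                           model_spec(terms = character(0), zi = fit$zi),
                           fit$offset_log, screen = FALSE)
  }
  max(0, min(1, 1 - fit$deviance / null_fit$deviance))
}

## rebuild the combined design for new data using the stored constructors
.predict_design <- function(fit, newdata) {
  .build_design(newdata, fit$terms, fit$spec$k, info = fit$design_info)$C
}

#' Standardized annual relative-abundance index
#'
#' For each survey year, every transect in the reference grid (by default the
#' pooled all-years covariate distribution of the fitting data) is assigned
#' that year, the expected count per unit effective area
#' E[y]/A = (1 - pi) lambda / A is predicted, averaged over the grid, and
#' scaled to the reporting area.
#'
#' @param fit a [fit_zipgam()] result (must include a `year` term).
#' @param newdata optional reference grid (defaults to the fitting data).
#' @param per_area_km2 reporting area (default 0.1 km^2).
#' @param offset_unit_km2 the area unit, in km^2, in which the fitting offsets
#'   were expressed (1 when offsets were log km^2).
#' @return data.frame with `year`, `index` (individuals per `per_area_km2`)
#'   and `se_log` (approximate link-scale SE from the penalized information).
#' @export
annual_index <- function(fit, newdata = NULL, per_area_km2 = 0.1,
                         offset_unit_km2 = 1) {
  if (!("year" %in% fit$terms)) stop_config("annual_index needs a year term in the fit")
  grid <- newdata %||% fit$data
  years <- as.integer(fit$design_info$year_levels)
  scale <- per_area_km2 / offset_unit_km2
  g1 <- if (fit$zi == "linked") fit$gamma[2] else 0
  Vp <- tryCatch(solve(fit$Hp), error = function(e) NULL)
  out <- lapply(years, function(yr) {
    gd <- grid
    gd$year <- yr
    C <- .predict_design(fit, gd)
    eta <- drop(C %*% fit$coefficients)
    p1 <- if (fit$zi == "none") rep(1, length(eta)) else {
      stats::plogis(fit$gamma[1] + g1 * eta)
    }
    mu <- p1 * exp(eta)
    v <- mean(mu)
    se_log <- NA_real_
    if (!is.null(Vp)) {
      h <- mu * (1 + (1 - p1) * g1)   # d mu / d eta
      a <- drop(crossprod(C, h)) / length(h)
      se_log <- sqrt(max(drop(a %*% Vp %*% a), 0)) / v
    }
    data.frame(year = yr, index = scale * v, se_log = se_log)
  })
  do.call(rbind, out)
}

#' Backward AIC selection of model terms
#'
#' Iteratively removes the term whose deletion most decreases conditional AIC
#' until no deletion helps, recording the path with likelihood-ratio
#' chi-square p-values for each nested comparison.
#'
#' @param data,spec,offset_log as in [fit_zipgam()].
#' @param keep terms never dropped (default `"year"`, which carries the
#'   index).
#' @param ... passed to [fit_zipgam()].
#' @return a `zipgam_fit` with a `selection_path` data.frame attached.
#' @export
backward_select <- function(data, spec = model_spec(), offset_log,
                            keep = "year", ...) {
  fit <- fit_zipgam(data, spec, offset_log, ...)
  path <- data.frame(step = 0L, dropped = "(full)", aic = fit$caic,
                     lrt_chi2 = NA_real_, lrt_df = NA_real_, lrt_p = NA_real_)
  step <- 0L
  repeat {
    droppable <- setdiff(fit$terms, keep)
    if (!length(droppable)) break
    cands <- lapply(droppable, function(tm) {
      sp <- fit$spec
      sp$terms <- setdiff(fit$terms, tm)
      fit_zipgam(data, sp, offset_log,
                 lambda_s = fit$lambda_s, lambda_u = fit$lambda_u,
                 screen = FALSE)
    })
    aics <- vapply(cands, `[[`, numeric(1), "caic")
    j <- which.min(aics)
    if (aics[j] >= fit$caic) break
    red <- cands[[j]]
    chi2 <- max(2 * (fit$loglik - red$loglik), 0)
    dfd <- max(fit$edf - red$edf, 1e-8)
    step <- step + 1L
    path <- rbind(path, data.frame(
      step = step, dropped = droppable[j], aic = red$caic,
      lrt_chi2 = chi2, lrt_df = dfd,
      lrt_p = stats::pchisq(chi2, dfd, lower.tail = FALSE)
    ))
    fit <- red
  }
  fit$selection_path <- path
  fit
}

#' @export
print.zipgam_fit <- function(x, ...) {
  cat("Zero-inflated Poisson GAM fit\n")
  cat(sprintf("  terms: %s\n", paste(x$terms, collapse = ", ")))
  cat(sprintf("  zero-inflation: %s", x$zi))
  if (x$zi != "none") cat(sprintf(" (gamma = %s)", paste(round(x$gamma, 3), collapse = ", ")))
  cat("\n")
  cat(sprintf("  loglik %.2f, edf %.2f, cAIC %.2f\n", x$loglik, x$edf, x$caic))
  cat(sprintf("  penalties: lambda_s %.3g, lambda_u %.3g\n", x$lambda_s, x$lambda_u))
  if (!is.na(x$observer_sd_hat)) {
    cat(sprintf("  observer effect SD (fitted): %.3f\n", x$observer_sd_hat))
  }
  invisible(x)
}
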