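#' Nonparametric bootstrap for the two-stage index estimator
#'
#' Uncertainty in the annual index comes from both the detection-function
#' stage and the count-model stage, so the whole pipeline is refitted on
#' datasets resampled with replacement, independently within each year. The
#' selected model STRUCTURE (detection key/adjustment/covariates and count
#' model terms, plus smoothing penalties) is held fixed across replicates;
#' only parameters are re-estimated. Per-year standard deviations over
#' replicates give the bootstrap standard errors (BSE) and the 2.5th/97.5th
#' percentiles the 95\% bootstrap confidence intervals (BCI).
#'
#' @name boot
NULL

#' Resample a dataset with replacement, independently per year
#'
#' Within each year, transects are drawn with replacement to the original
#' per-year count. Sightings travel with their transect; every resampled copy
#' receives a fresh unique transect id so duplicated transects stay distinct.
#'
#' @param transects,sightings the dataset to resample.
#' @param seed RNG seed.
#' @return list with resampled `transects` and `sightings`.
#' @export
resample_dataset <- function(transects, sightings, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(transects)), transects$year),
                       function(ii) ii[sample.int(length(ii), length(ii),
                                                  replace = TRUE)]),
                use.names = FALSE)
  tr <- transects[idx, , drop = FALSE]
  old_id <- tr$transect_id
  new_id <- sprintf("%s_r%05d", old_id, seq_along(old_id))
  tr$transect_id <- new_id
  rownames(tr) <- NULL

  sg_by_tr <- split(seq_len(nrow(sightings)), sightings$transect_id)
  pick <- sg_by_tr[old_id]
  reps <- lengths(pick)
  has <- reps > 0
  if (any(has)) {
    rows <- unlist(pick[has], use.names = FALSE)
    sg <- sightings[rows, , drop = FALSE]
    sg$transect_id <- rep(new_id[has], reps[has])
    sg$sighting_id <- sprintf("%s_r%06d", sg$sighting_id, seq_len(nrow(sg)))
    rownames(sg) <- NULL
  } else {
    sg <- sightings[0, , drop = FALSE]
  }
  list(transects = tr, sightings = sg)
}

#' Bootstrap the detection + ZIP-GAM pipeline
#'
#' For each replicate: resample per year, re-bin the smeared sightings, refit
#' the detection parameters (structure fixed to `det_model`), recompute
#' effective-area offsets, refit the count model (terms and penalties fixed to
#' `fit`), and store the annual indices. Non-converged replicates are dropped
#' and counted.
#'
#' @param transects,sightings the QC-filtered point-estimate dataset.
#' @param det_model the selected [fit_detection()] model.
#' @param fit the selected [fit_zipgam()] model.
#' @param smear a [smear_config()]; @param bins a [bin_scheme()].
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed master seed; each replicate gets an independent child seed, so
#'   results do not depend on execution order.
#' @param per_area_km2 reporting area for the indices.
#' @return object of class `bootstrap_result` with `annual_index_reps`
#'   (reps x years), `bse`, `bci` (2.5/97.5 percentiles), and `failures`.
#' @export
bootstrap_pipeline <- function(transects, sightings, det_model, fit,
                               smear = smear_config(), bins = bin_scheme(),
                               n_reps = 1000L, seed = 1L, per_area_km2 = 0.1) {
  years <- sort(unique(transects$year))
  seeds <- child_seeds(seed, n_reps)
  sw_km <- strip_width(bins$truncation_m) / 1000

  cand <- list(list(key = det_model$key, adjustment = det_model$adjustment,
                    adj_order = length(det_model$adj_coefs),
                    covars = det_model$covars))
  reps <- matrix(NA_real_, n_reps, length(years),
                 dimnames = list(NULL, years))
  failures <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      rs <- resample_dataset(transects, sightings, seed = seeds[r])
      binned <- bin_sightings(rs$sightings, rs$transects, smear, bins)
      dm <- fit_detection(binned, candidates = cand)
      p_hat <- predict_p(dm, rs$transects)
      ok <- is.finite(p_hat) & p_hat > 0
      tr <- rs$transects[ok, , drop = FALSE]
      off <- log(effective_area(tr$length_km, sw_km, p_hat[ok]))
      f <- fit_zipgam(tr, fit$spec_for_boot %||% .boot_spec(fit), off,
                      lambda_s = fit$lambda_s, lambda_u = fit$lambda_u,
                      screen = FALSE, start = fit$par)
      ai <- annual_index(f, per_area_km2 = per_area_km2)
      ai$index[match(years, ai$year)]
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) failures <- failures + 1L else reps[r, ] <- res
  }
  ok <- stats::complete.cases(reps)
  if (failures > n_reps / 2) stop_config("more than half of bootstrap replicates failed")
  if (failures > n_reps / 10) {
    warning(sprintf("%d of %d bootstrap replicates failed", failures, n_reps),
            call. = FALSE)
  }
  good <- reps[ok, , drop = FALSE]
  structure(
    list(
      n_reps = n_reps,
      annual_index_reps = good,
      bse = apply(good, 2, stats::sd),
      bci = t(apply(good, 2, stats::quantile, probs = c(0.025, 0.975))),
      failures = failures,
      years = years, seed = seed
    ),
    class = "bootstrap_result"
  )
}

.boot_spec <- function(fit) {
  sp <- fit$spec
  sp$terms <- fit$terms
  sp
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n", x$n_reps, x$failures))
  tab <- data.frame(year = x$years, bse = round(x$bse, 4),
                    bci_lo = round(x$bci[, 1], 4), bci_hi = round(x$bci[, 2], 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
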