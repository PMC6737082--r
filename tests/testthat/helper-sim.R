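# Shared fixtures, built in code.

# a constant nest series long enough for any lag under test
flat_nests <- function(value = 50000) {
  data.frame(year = 1980:2040, nest_count = value)
}

# distances drawn from the detection-conditioned density on [0, w]
# (rejection sampling), returned as a sighting table at 90 degrees so the
# perpendicular distance equals the draw; single parent transect.
sim_detected_distances <- function(n, w = 100, seed = 1,
                                   gfun = function(d) hazard_rate_g(d, 30, 3)) {
  set.seed(seed)
  d <- numeric(0)
  while (length(d) < n) {
    cand <- stats::runif(2 * n, 0, w)
    keep <- stats::runif(2 * n) < gfun(cand)
    d <- c(d, cand[keep])
  }
  data.frame(
    sighting_id = sprintf("s%06d", seq_len(n)), transect_id = "t1",
    radial_m = pmax(d[seq_len(n)], 0.1), angle_deg = 90, n_individuals = 1,
    stringsAsFactors = FALSE
  )
}

one_transect <- function() {
  data.frame(transect_id = "t1", beaufort = 1, glare = "none",
             speed_kmh = 12, stringsAsFactors = FALSE)
}

no_smear <- function() smear_config(phi_deg = 0, s_prop = 0)

cds_hazard_candidate <- function(covars = character(0)) {
  list(list(key = "hazard_rate", adjustment = "none", adj_order = 0L,
            covars = covars))
}

# run sim -> qc -> detection -> offsets for a config; returns the pieces the
# count-model tests need
pipeline_to_offsets <- function(cfg, candidates = cds_hazard_candidate("beaufort")) {
  d <- simulate_fleet(cfg)
  qc <- qc_pipeline(d$transects, d$sightings)
  binned <- bin_sightings(qc$sightings, qc$transects)
  dm <- fit_detection(binned, candidates = candidates)
  p <- predict_p(dm, qc$transects)
  ok <- is.finite(p) & p > 0
  tr <- qc$transects[ok, , drop = FALSE]
  sg <- qc$sightings[qc$sightings$transect_id %in% tr$transect_id, , drop = FALSE]
  list(
    dataset = d, qc = qc, detection = dm,
    transects = tr, sightings = sg,
    offset_log = log(effective_area(tr$length_km, 0.2, p[ok]))
  )
}
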