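## Internal helpers shared across modules.

DEG2RAD <- pi / 180
EARTH_RADIUS_KM <- 6371.0088

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Project WGS84 coordinates to a local equal-area plane
#'
#' Lambert cylindrical equal-area projection about a local origin, in
#' kilometres. Equal-area is required so that kernel-density contour areas and
#' enclosed probability masses are meaningful.
#'
#' @param lon,lat numeric vectors, decimal degrees (WGS84).
#' @param origin optional list with `lon0`, `lat0` (degrees); defaults to the
#'   centroid of the input points.
#' @return list with `x`, `y` (km) and the `origin` used.
#' @keywords internal
project_equal_area <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) {
    origin <- list(lon0 = mean(lon, na.rm = TRUE), lat0 = mean(lat, na.rm = TRUE))
  }
  cl0 <- cos(origin$lat0 * DEG2RAD)
  x <- EARTH_RADIUS_KM * (lon - origin$lon0) * DEG2RAD * cl0
  y <- EARTH_RADIUS_KM * sin(lat * DEG2RAD) / cl0
  list(x = x, y = y, origin = origin)
}

.gl_cache <- new.env(parent = emptyenv())

## Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch); cached per n on the
## reference interval because the detection likelihood calls this in its
## innermost loop.
gauss_legendre <- function(n, a = 0, b = 1) {
  key <- as.character(n)
  if (!is.null(g <- .gl_cache[[key]])) {
    return(list(nodes = (b - a) / 2 * g$x + (a + b) / 2,
                weights = (b - a) / 2 * g$w))
  }
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  ## cache on [-1, 1]
  .gl_cache[[key]] <- list(x = x[ord], w = w[ord])
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2, weights = (b - a) / 2 * w[ord])
}

## Small deterministic content hash (FNV-1a, 32 bit) for provenance stamps.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

## Derive a stream of independent child seeds from one master seed without
## disturbing the caller's RNG state.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_config("%s is missing mandatory column(s): %s", what, paste(miss, collapse = ", "))
  }
}
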