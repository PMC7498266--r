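# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so that seeded generators do not perturb user code.
#' A `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed (keeps each stage's
# randomness independent while remaining reproducible from one integer).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Significance stars
#'
#' Standard star coding used throughout the figures of this field:
#' `ns` for p >= 0.05, `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
#' @examples
#' pStars(c(0.2, 0.04, 0.004, 1e-5))
pStars <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}

# Centered moving mean with shrinking windows at the edges.
movingMean <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 2L) return(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Linear interpolation of a trace onto a complete frame grid; used for
# smoothing only, never for amplitude measurement.
interpToGrid <- function(timeMin, x, frameIntervalMin) {
  grid <- seq(min(timeMin), max(timeMin), by = frameIntervalMin)
  if (length(grid) == length(timeMin)) return(list(time = timeMin, x = x))
  xi <- stats::approx(timeMin, x, xout = grid, method = "linear")$y
  list(time = grid, x = xi)
}

# FNV-1a 32-bit hash of a character scalar or raw vector; used for
# config/output fingerprints in run manifests (no cryptographic intent).
fnv1a32 <- function(s) {
  bytes <- if (is.raw(s)) as.integer(s)
           else as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0x811C9DC5
  for (b in bytes) {
    h <- bitwXor(h, b)
    # 32-bit modular multiply by the FNV prime 16777619
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# Estimate the sampling interval of a time grid; errors on non-uniform grids
# whose gaps are not integer multiples of the base interval.
inferFrameInterval <- function(timeMin) {
  d <- diff(timeMin)
  if (length(d) == 0L) return(NA_real_)
  base <- min(d)
  if (any(abs(d / base - round(d / base)) > 1e-6))
    stop("time gaps are not integer multiples of the frame interval")
  base
}
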