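#' @useDynLib nirsdip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma rnorm convolve sd var
#' @importFrom utils modifyList
NULL

# Run `expr` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic scheme used to give each channel / noise component its own
#' RNG stream: `(master + 1000003 * i + 7919 * j) mod (2^31 - 1)`.
#'
#' @param master master seed (integer-valued scalar).
#' @param i,j non-negative integer indices (e.g. channel and component).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i = 0L, j = 0L) {
  as.integer((abs(as.numeric(master)) + 1000003 * as.numeric(i) +
                7919 * as.numeric(j)) %% 2147483647)
}

#' Convert a prediction horizon in samples to seconds
#'
#' Reports the lead time `q / fs`. Human-readable horizon labels truncate to
#' two decimals (so 15 steps at 9.19 Hz is reported as 1.63 s and 20 steps
#' as 2.17 s); the single-sample latency granularity `1 / fs` is
#' conventionally *rounded* to two decimals instead (0.11 s at 9.19 Hz).
#'
#' @param q horizon in samples (positive integer, vectorized).
#' @param fs sampling rate in Hz.
#' @param digits decimals kept when truncating; `NULL` returns the exact value.
#' @return Horizon in seconds.
#' @export
steps_to_seconds <- function(q, fs, digits = 2L) {
  stopifnot(fs > 0, all(q >= 0))
  x <- q / fs
  if (is.null(digits)) x else trunc(x * 10^digits) / 10^digits
}

#' Minimum achievable detection latency
#'
#' One sample period, rounded to two decimals: the granularity with which any
#' sample-based detector can time-stamp an event (0.11 s at 9.19 Hz).
#'
#' @param fs sampling rate in Hz.
#' @return Latency in seconds.
#' @export
latency_granularity <- function(fs) {
  stopifnot(fs > 0)
  round(1 / fs, 2L)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  invisible(x)
}
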