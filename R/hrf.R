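#' Three-gamma hemodynamic response function parameters
#'
#' The canonical HRF is modeled as a linear combination of three gamma
#' densities: a small negative early lobe (the initial dip), the main
#' positive response peaking around 5 s, and a late negative undershoot.
#' A two-gamma HRF cannot represent the initial dip; the third lobe is the
#' extra degree of freedom that makes early-dip modeling possible.
#'
#' @param amplitudes numeric(3), lobe amplitudes `A_j` (dimensionless).
#'   Defaults `c(-1.5, 7, -2)`: dip, main response, undershoot.
#' @param shapes numeric(3), gamma shape parameters `alpha_j` (> 0;
#'   `alpha_j > 1` is required for the response to start at zero).
#'   Defaults `c(1.5, 6, 16)`.
#' @param scales numeric(3), gamma rate parameters `beta_j` in 1/s (> 0).
#'   Defaults `c(1, 1, 1)`.
#' @return An object of class `hrf_params`.
#' @seealso [canonical_hrf()], [desired_hrf()]
#' @export
hrf_params <- function(amplitudes = c(-1.5, 7, -2),
                       shapes = c(1.5, 6, 16),
                       scales = c(1, 1, 1)) {
  if (length(amplitudes) != 3L || length(shapes) != 3L || length(scales) != 3L)
    stop("`amplitudes`, `shapes` and `scales` must each have length 3",
         call. = FALSE)
  assert_finite(c(amplitudes, shapes, scales), "hrf_params fields")
  if (any(shapes <= 0)) stop("all shape parameters must be > 0", call. = FALSE)
  if (any(scales <= 0)) stop("all scale parameters must be > 0", call. = FALSE)
  structure(list(amplitudes = as.numeric(amplitudes),
                 shapes = as.numeric(shapes),
                 scales = as.numeric(scales)),
            class = "hrf_params")
}

#' Sample the canonical three-gamma HRF
#'
#' Evaluates `h(t) = sum_j A_j t^(alpha_j - 1) beta_j^alpha_j
#' exp(-beta_j t) / Gamma(alpha_j)` at sample times `t = n / fs` seconds,
#' `n = 0, ..., floor(duration_s * fs) - 1`. Each term is `A_j` times a
#' gamma density, so [stats::dgamma()] does the evaluation.
#'
#' @param params an [hrf_params()] object.
#' @param duration_s kernel duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @return Numeric vector of HRF values with attributes `fs` and `time_s`.
#' @examples
#' h <- canonical_hrf(hrf_params(), duration_s = 30, fs = 9.19)
#' @export
canonical_hrf <- function(params = hrf_params(), duration_s, fs) {
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, params)
  stopifnot(duration_s > 0, fs > 0)
  n <- floor(duration_s * fs)
  t <- seq_len(n) - 1
  t <- t / fs
  h <- numeric(n)
  for (j in 1:3)
    h <- h + params$amplitudes[j] *
      dgamma(t, shape = params$shapes[j], rate = params$scales[j])
  attr(h, "fs") <- fs
  attr(h, "time_s") <- t
  h
}

#' Task/rest stimulation boxcar
#'
#' Binary stimulus sequence `s(k)` that is 1 while the subject performs the
#' task and 0 at rest. Trials are tiled back to back: each trial contributes
#' `floor((task_s + rest_s) * fs)` samples, of which the samples whose
#' within-trial time lies in `[0, task_s)` are task. An optional leading
#' rest-only segment (used for threshold calibration) can be prepended.
#'
#' @param fs sampling rate in Hz.
#' @param task_s task duration per trial in seconds (default 10).
#' @param rest_s rest duration per trial in seconds (default 20).
#' @param n_trials number of trials (default 6).
#' @param lead_rest_s rest-only prefix in seconds (default 0).
#' @return An object of class `stimulus`: list with `s` (0/1 vector), `fs`,
#'   `onsets_s` (task onsets in seconds), `task_s`, `rest_s`, `n_trials`.
#' @export
stimulus_boxcar <- function(fs, task_s = 10, rest_s = 20, n_trials = 6,
                            lead_rest_s = 0) {
  stopifnot(fs > 0, task_s >= 0, rest_s >= 0, n_trials >= 0, lead_rest_s >= 0)
  n_lead <- floor(lead_rest_s * fs)
  n_trial <- floor((task_s + rest_s) * fs)
  local_t <- (seq_len(n_trial) - 1) / fs
  trial <- as.integer(local_t < task_s)
  s <- c(integer(n_lead), rep(trial, n_trials))
  onsets <- if (n_trials > 0)
    lead_rest_s + (0:(n_trials - 1)) * (task_s + rest_s) else numeric(0)
  structure(list(s = s, fs = fs, onsets_s = onsets, task_s = task_s,
                 rest_s = rest_s, n_trials = n_trials,
                 lead_rest_s = lead_rest_s),
            class = "stimulus")
}

#' Stimulus sequence from explicit task blocks
#'
#' General form of [stimulus_boxcar()] for irregular paradigms: task blocks
#' given by start times and durations on a grid of `floor(total_s * fs)`
#' samples. A sample is task iff its time lies in `[start, start + len)` for
#' some block. Overlapping blocks are rejected.
#'
#' @param starts_s,lens_s numeric vectors of block starts and durations (s).
#' @param total_s total duration in seconds.
#' @param fs sampling rate in Hz.
#' @return A `stimulus` object (with `task_s`/`rest_s` set to `NA`).
#' @export
boxcar_from_blocks <- function(starts_s, lens_s, total_s, fs) {
  stopifnot(length(starts_s) == length(lens_s), fs > 0, total_s > 0,
            all(lens_s >= 0), all(starts_s >= 0))
  o <- order(starts_s)
  starts_s <- starts_s[o]; lens_s <- lens_s[o]
  if (length(starts_s) > 1 &&
      any(starts_s[-1] < (starts_s + lens_s)[-length(starts_s)]))
    stop("task blocks overlap", call. = FALSE)
  n <- floor(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  s <- integer(n)
  for (b in seq_along(starts_s))
    s[t >= starts_s[b] & t < starts_s[b] + lens_s[b]] <- 1L
  structure(list(s = s, fs = fs, onsets_s = starts_s, task_s = NA_real_,
                 rest_s = NA_real_, n_trials = length(starts_s),
                 lead_rest_s = 0),
            class = "stimulus")
}

#' Desired hemodynamic response (dHRF)
#'
#' Convolves the canonical HRF with the stimulation boxcar,
#' `u(k) = sum_{l=0}^{k} h(l) s(k - l)`, truncated to the stimulus length.
#' This is the regression input `u` of the brain-activity model: the
#' response a task-locked channel is expected to follow. With
#' `normalize = TRUE` (default) `u` is scaled to unit peak magnitude so
#' model coefficients absorb the response amplitude.
#'
#' @param h sampled HRF from [canonical_hrf()] (carries its `fs`).
#' @param s a `stimulus` object sampled at the same rate.
#' @param normalize divide by `max(abs(u))` (no-op on an all-zero `u`).
#' @return Object of class `dhrf`: list with `u`, `fs`, `normalized`,
#'   and the originating `stimulus`.
#' @export
desired_hrf <- function(h, s, normalize = TRUE) {
  stopifnot(inherits(s, "stimulus"), length(h) > 0)
  fs_h <- attr(h, "fs")
  if (!is.null(fs_h) && !isTRUE(all.equal(fs_h, s$fs)))
    stop("sampling rates of `h` and `s` differ", call. = FALSE)
  u <- causal_convolve(as.numeric(h), as.numeric(s$s))
  if (normalize) {
    m <- max(abs(u))
    if (m > 0) u <- u / m
  }
  structure(list(u = u, fs = s$fs, normalized = normalize, stimulus = s),
            class = "dhrf")
}

# FFT-based causal convolution truncated to length(x): y[k] = sum h[l] x[k-l].
causal_convolve <- function(h, x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  convolve(x, rev(h), type = "open")[seq_len(n)]
}

#' Initial-dip response component
#'
#' Transient dip locked to each task onset: the negative early lobe of the
#' canonical HRF (the part of `h` before its main peak, clipped to
#' negative values) is convolved with a unit impulse at every task onset
#' and normalized to a minimum of -1. The initial dip is a brief
#' oxygen-extraction transient that precedes the blood-flow response
#' (literature peak around 2 s), so it responds to the onset of activity
#' rather than tracking the full task block. Used by the synthetic
#' generator to inject a controllable dip that is shape-consistent with
#' the three-gamma model.
#'
#' @inheritParams desired_hrf
#' @return A `dhrf`-like object whose `u` is <= 0 with minimum -1 (or all
#'   zero if the HRF has no negative early lobe).
#' @export
dip_response <- function(h, s) {
  stopifnot(inherits(s, "stimulus"))
  h <- as.numeric(h)
  peak <- which.max(h)
  early <- pmin(h, 0)
  if (peak < length(h)) early[peak:length(h)] <- 0
  sv <- as.numeric(s$s)
  onsets <- as.numeric(diff(c(0, sv)) > 0)   # impulse at each 0 -> 1 edge
  d <- causal_convolve(early, onsets)
  m <- min(d)
  if (m < 0) d <- d / abs(m)
  structure(list(u = d, fs = s$fs, normalized = TRUE, stimulus = s),
            class = "dhrf")
}
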