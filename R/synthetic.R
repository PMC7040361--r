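#' Physiological noise parameters
#'
#' Structured noise added to every synthetic channel: three sinusoids for
#' cardiac pulsation, Mayer waves and respiration, a linear drift, and
#' i.i.d. Gaussian measurement noise. Default frequencies sit in the
#' standard physiological bands (cardiac ~1 Hz, respiration ~0.25 Hz,
#' Mayer ~0.1 Hz); note the Mayer band lies *inside* the 0.01-0.15 Hz
#' analysis pass-band, so filtering attenuates but does not remove it.
#'
#' @param cardiac,mayer,respiration numeric(3) each: `c(amplitude, freq_hz,
#'   phase_rad)`; amplitudes in signal units (a.u.), frequencies in Hz.
#' @param sd standard deviation of the Gaussian noise (a.u., >= 0).
#' @param drift linear drift slope in a.u. per second.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(cardiac = c(0.25, 1.0, 0),
                         mayer = c(0.10, 0.1, 0),
                         respiration = c(0.15, 0.25, 0),
                         sd = 0.15, drift = 0.002) {
  comp <- rbind(cardiac = cardiac, mayer = mayer, respiration = respiration)
  if (ncol(comp) != 3L) stop("each component needs (amp, freq, phase)",
                             call. = FALSE)
  colnames(comp) <- c("amp", "freq_hz", "phase_rad")
  assert_finite(c(comp, sd, drift), "noise_params fields")
  if (any(comp[, "amp"] < 0) || sd < 0)
    stop("amplitudes and sd must be >= 0", call. = FALSE)
  if (any(comp[, "freq_hz"] <= 0))
    stop("frequencies must be > 0", call. = FALSE)
  structure(list(components = comp, sd = sd, drift = drift),
            class = "noise_params")
}

#' Generate one channel's structured + random noise
#'
#' Sum of the three physiological sinusoids, the linear drift, and Gaussian
#' noise drawn under `seed`. A pure function of its arguments: the same seed
#' yields a bit-identical series.
#'
#' @param params a [noise_params()] object.
#' @param n number of samples (>= 0).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed for the Gaussian component.
#' @return Numeric vector of length `n`.
#' @export
generate_noise <- function(params, n, fs, seed = 0L) {
  stopifnot(inherits(params, "noise_params"), n >= 0, fs > 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  t <- (seq_len(n) - 1) / fs
  out <- params$drift * t
  for (i in seq_len(nrow(params$components))) {
    cmp <- params$components[i, ]
    if (cmp[["amp"]] > 0)
      out <- out + cmp[["amp"]] *
        sin(2 * pi * cmp[["freq_hz"]] * t + cmp[["phase_rad"]])
  }
  if (params$sd > 0)
    out <- out + with_seed(seed, rnorm(n, 0, params$sd))
  out
}

#' Per-channel generative specification
#'
#' Describes how one optode channel responds to the task. Active channels
#' carry the task-locked response (and optionally an initial dip);
#' non-active channels are pure noise. The deoxyhemoglobin series mirrors
#' the oxyhemoglobin response with a negative gain, and its dip component
#' is mirrored positively with ratio `dip_mirror` (< 1, so the pure-dip
#' trajectory has negative blood-volume change and lands in the canonical
#' dip phases of the phase plane).
#'
#' @param id channel id (integer >= 1).
#' @param active logical; non-active channels must have `hbo_gain = 0`.
#' @param hbo_gain HbO response gain (a.u.).
#' @param hbr_gain HbR response gain; default `-0.3 * hbo_gain`.
#' @param dip_gain amplitude of the injected initial dip (a.u., >= 0).
#' @param dip_mirror HbR dip mirror ratio (default 0.6).
#' @param onset_jitter_s response onset shift in seconds (default 0).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(id, active = TRUE, hbo_gain = if (active) 1 else 0,
                         hbr_gain = -0.3 * hbo_gain, dip_gain = 0,
                         dip_mirror = 0.6, onset_jitter_s = 0) {
  stopifnot(id >= 1)
  if (active && hbo_gain == 0)
    stop("active channels need a nonzero `hbo_gain`", call. = FALSE)
  if (!active && hbo_gain != 0)
    stop("non-active channels must have `hbo_gain = 0`", call. = FALSE)
  assert_finite(c(hbo_gain, hbr_gain, dip_gain, dip_mirror, onset_jitter_s),
                "channel_spec fields")
  structure(list(id = as.integer(id), active = isTRUE(active),
                 hbo_gain = hbo_gain, hbr_gain = hbr_gain,
                 dip_gain = dip_gain, dip_mirror = dip_mirror,
                 onset_jitter_s = onset_jitter_s),
            class = "channel_spec")
}

shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0L || n == 0L) return(x)
  if (k > 0) c(numeric(min(k, n)), x)[seq_len(n)]
  else c(x[-seq_len(min(-k, n))], numeric(min(-k, n)))
}

#' Generate one channel's HbO/HbR pair
#'
#' Realizes the generative model: `HbO = hbo_gain * u + dip_gain * d +
#' noise`, `HbR = hbr_gain * u - dip_mirror * dip_gain * d + noise'`, where
#' `u` is the desired HRF, `d` the (negative-going, unit-depth) dip
#' response, and the two noise draws are independent with sub-seeds derived
#' deterministically from `seed` (see [derive_seed()]).
#'
#' @param spec a [channel_spec()].
#' @param dhrf a `dhrf` object from [desired_hrf()].
#' @param dip a `dhrf`-like object from [dip_response()], or `NULL` for none.
#' @param noise a [noise_params()] object.
#' @param seed master seed for this channel.
#' @return List with numeric vectors `hbo` and `hbr`.
#' @export
generate_channel <- function(spec, dhrf, dip = NULL, noise = noise_params(),
                             seed = 0L) {
  stopifnot(inherits(spec, "channel_spec"), inherits(dhrf, "dhrf"))
  u <- dhrf$u
  d <- if (is.null(dip)) numeric(length(u)) else dip$u
  stopifnot(length(d) == length(u))
  jit <- as.integer(round(spec$onset_jitter_s * dhrf$fs))
  if (jit != 0L) {
    u <- shift_series(u, jit)
    d <- shift_series(d, jit)
  }
  hbo <- spec$hbo_gain * u + spec$dip_gain * d +
    generate_noise(noise, length(u), dhrf$fs, derive_seed(seed, spec$id, 1L))
  hbr <- spec$hbr_gain * u - spec$dip_mirror * spec$dip_gain * d +
    generate_noise(noise, length(u), dhrf$fs, derive_seed(seed, spec$id, 2L))
  list(hbo = hbo, hbr = hbr)
}

#' Synthetic recording configuration
#'
#' Defaults emulate the finger-tapping study design the detector targets:
#' 9.19 Hz sampling, a 30 s resting prefix, two sessions of six 30 s trials
#' (10 s task + 20 s rest), 36 channels with a six-channel active motor
#' montage. Gains are in arbitrary concentration units; active channels get
#' a +/-20% per-channel gain jitter so the montage is not perfectly uniform.
#'
#' @param fs sampling rate (Hz).
#' @param task_s,rest_s,n_trials per-trial paradigm.
#' @param n_sessions number of task sessions.
#' @param rest_prefix_s leading resting-state segment (s), used for
#'   threshold calibration.
#' @param n_channels total channel count.
#' @param active_channels integer ids of task-responsive channels.
#' @param hbo_gain,hbr_ratio,dip_gain,dip_mirror response amplitudes:
#'   HbR gain is `hbr_ratio * hbo_gain`.
#' @param gain_jitter relative sd-free uniform jitter half-width on active
#'   gains (0.2 = +/-20%).
#' @param hrf an [hrf_params()] object.
#' @param hrf_duration_s length of the sampled HRF kernel (s).
#' @param noise a [noise_params()] object.
#' @return An object of class `synth_config` (a named list).
#' @export
synth_config <- function(fs = 9.19, task_s = 10, rest_s = 20, n_trials = 6,
                         n_sessions = 2, rest_prefix_s = 30, n_channels = 36,
                         active_channels = c(17L, 18L, 21L, 29L, 30L, 33L),
                         hbo_gain = 1.0, hbr_ratio = -0.3, dip_gain = 0.3,
                         dip_mirror = 0.6, gain_jitter = 0.2,
                         hrf = hrf_params(), hrf_duration_s = 30,
                         noise = noise_params()) {
  stopifnot(fs > 0, n_channels >= 1, n_sessions >= 1,
            all(active_channels >= 1), all(active_channels <= n_channels))
  structure(list(fs = fs, task_s = task_s, rest_s = rest_s,
                 n_trials = n_trials, n_sessions = n_sessions,
                 rest_prefix_s = rest_prefix_s, n_channels = n_channels,
                 active_channels = as.integer(active_channels),
                 hbo_gain = hbo_gain, hbr_ratio = hbr_ratio,
                 dip_gain = dip_gain, dip_mirror = dip_mirror,
                 gain_jitter = gain_jitter, hrf = hrf,
                 hrf_duration_s = hrf_duration_s, noise = noise),
            class = "synth_config")
}

#' Generate a complete synthetic fNIRS recording
#'
#' Builds the global stimulus (resting prefix followed by the task
#' sessions), the desired HRF and dip responses, and every channel's
#' HbO/HbR pair. The result is a pure function of `(config, seed)`.
#'
#' @param config a [synth_config()].
#' @param seed master seed.
#' @return An object of class `fnirs_record`: list with matrices `hbo`,
#'   `hbr` (`n x n_channels`), `time_s`, `fs`, `segments` (data.frame with
#'   `segment`, `start`, `end` sample indices, 1-based inclusive),
#'   `stimulus`, `active_channels`, `config`, `seed`.
#' @export
generate_dataset <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n_rest <- floor(config$rest_prefix_s * fs)
  n_trial <- floor((config$task_s + config$rest_s) * fs)
  n_session <- n_trial * config$n_trials
  stim <- stimulus_boxcar(fs, config$task_s, config$rest_s,
                          config$n_trials * config$n_sessions,
                          lead_rest_s = config$rest_prefix_s)
  h <- canonical_hrf(config$hrf, config$hrf_duration_s, fs)
  dhrf <- desired_hrf(h, stim, normalize = TRUE)
  dip <- dip_response(h, stim)
  n <- length(dhrf$u)

  gains <- numeric(config$n_channels)
  act <- config$active_channels
  jit <- with_seed(derive_seed(seed, 0L, 99L),
                   stats::runif(length(act), 1 - config$gain_jitter,
                                1 + config$gain_jitter))
  gains[act] <- config$hbo_gain * jit

  hbo <- matrix(0, n, config$n_channels)
  hbr <- matrix(0, n, config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    sp <- channel_spec(ch, active = ch %in% act, hbo_gain = gains[ch],
                       hbr_gain = config$hbr_ratio * gains[ch],
                       dip_gain = if (ch %in% act) config$dip_gain else 0,
                       dip_mirror = config$dip_mirror)
    xy <- generate_channel(sp, dhrf, dip, config$noise, seed)
    hbo[, ch] <- xy$hbo
    hbr[, ch] <- xy$hbr
  }
  segs <- data.frame(
    segment = c("rest", paste0("session", seq_len(config$n_sessions))),
    start = c(1L, n_rest + 1L + (seq_len(config$n_sessions) - 1L) * n_session),
    end = c(n_rest, n_rest + seq_len(config$n_sessions) * n_session))
  colnames(hbo) <- colnames(hbr) <- sprintf("ch%02d", seq_len(config$n_channels))
  structure(list(hbo = hbo, hbr = hbr, time_s = (seq_len(n) - 1) / fs,
                 fs = fs, segments = segs, stimulus = stim,
                 active_channels = act, config = config,
                 seed = as.integer(seed)),
            class = "fnirs_record")
}

#' @export
print.fnirs_record <- function(x, ...) {
  cat(sprintf("<fnirs_record> %d channels x %d samples @ %.2f Hz (%.1f s)\n",
              ncol(x$hbo), nrow(x$hbo), x$fs, nrow(x$hbo) / x$fs))
  cat("segments:\n")
  print(x$segments, row.names = FALSE)
  if (length(x$active_channels))
    cat("active channels:", paste(x$active_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Sample indices of a record segment
#'
#' @param record an `fnirs_record`.
#' @param segment segment name as in `record$segments` (e.g. `"rest"`,
#'   `"session1"`).
#' @return Integer vector of 1-based sample indices.
#' @export
segment_indices <- function(record, segment) {
  i <- match(segment, record$segments$segment)
  if (is.na(i)) stop(sprintf("no segment '%s' in record", segment),
                     call. = FALSE)
  seq.int(record$segments$start[i], record$segments$end[i])
}
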