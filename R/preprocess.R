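#' Band-pass filter specification
#'
#' Defaults follow standard fNIRS practice for isolating the task-evoked
#' hemodynamics: a cascade of fourth-order Butterworth low-pass (0.15 Hz)
#' and high-pass (0.01 Hz) sections, removing cardiac/respiratory
#' oscillations above the band and slow drift below it. `mode = "causal"`
#' filters forward only (required for online prediction, introduces phase
#' lag); `mode = "zero-phase"` uses forward-backward filtering for offline
#' analysis.
#'
#' @param low high-pass cutoff in Hz (default 0.01).
#' @param high low-pass cutoff in Hz (default 0.15).
#' @param order filter order of each section (default 4).
#' @param mode `"causal"` or `"zero-phase"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.01, high = 0.15, order = 4L,
                        mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  stopifnot(low > 0, high > low, order >= 1)
  structure(list(low = low, high = high, order = as.integer(order),
                 mode = mode),
            class = "filter_spec")
}

#' Band-pass filter a single series
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz; `spec$high` must be below `fs / 2`.
#' @param spec a [filter_spec()].
#' @return Filtered vector of the same length.
#' @export
bandpass_series <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  if (spec$high >= fs / 2)
    stop("high cutoff must be below the Nyquist frequency", call. = FALSE)
  lp <- signal::butter(spec$order, spec$high / (fs / 2), type = "low")
  hp <- signal::butter(spec$order, spec$low / (fs / 2), type = "high")
  if (spec$mode == "causal") {
    y <- signal::filter(lp, x)
    y <- signal::filter(hp, as.numeric(y))
  } else {
    y <- signal::filtfilt(lp, x)
    y <- signal::filtfilt(hp, as.numeric(y))
  }
  as.numeric(y)
}

#' Band-pass filter every channel of a recording
#'
#' Applies [bandpass_series()] independently to each channel's HbO and HbR
#' series; all annotations are preserved.
#'
#' @param record an `fnirs_record`.
#' @param spec a [filter_spec()].
#' @return The filtered `fnirs_record` (with attribute `filtered = TRUE`).
#' @export
bandpass <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "fnirs_record"))
  record$hbo <- apply(record$hbo, 2, bandpass_series, fs = record$fs,
                      spec = spec)
  record$hbr <- apply(record$hbr, 2, bandpass_series, fs = record$fs,
                      spec = spec)
  record$filter <- spec
  record
}
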