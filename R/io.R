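#' Write a recording to CSV with a JSON sidecar
#'
#' Wide CSV: `time_s, ch01_hbo, ch01_hbr, ..., chNN_hbo, chNN_hbr`. The
#' sidecar (`<path>.json` by default) stores the sampling rate, paradigm,
#' segment boundaries, active channels and generation seed, so a record
#' round-trips losslessly (values to better than 1e-12).
#'
#' @param record an `fnirs_record`.
#' @param path CSV output path.
#' @param sidecar sidecar JSON path (default `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(record, "fnirs_record"))
  nch <- ncol(record$hbo)
  df <- data.frame(time_s = record$time_s)
  for (ch in seq_len(nch)) {
    df[[sprintf("ch%02d_hbo", ch)]] <- record$hbo[, ch]
    df[[sprintf("ch%02d_hbr", ch)]] <- record$hbr[, ch]
  }
  data.table::fwrite(df, path)
  cfg <- record$config
  meta <- list(
    fs = record$fs,
    n_channels = nch,
    segments = record$segments,
    active_channels = record$active_channels,
    seed = record$seed,
    paradigm = if (!is.null(cfg))
      list(task_s = cfg$task_s, rest_s = cfg$rest_s, n_trials = cfg$n_trials,
           n_sessions = cfg$n_sessions, rest_prefix_s = cfg$rest_prefix_s)
      else NULL,
    hrf = if (!is.null(cfg))
      list(amplitudes = cfg$hrf$amplitudes, shapes = cfg$hrf$shapes,
           scales = cfg$hrf$scales, duration_s = cfg$hrf_duration_s)
      else NULL)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_record()]
#'
#' @param path CSV path; the sidecar JSON must sit at
#'   `paste0(path, ".json")` unless given explicitly.
#' @param sidecar sidecar JSON path.
#' @return An `fnirs_record`.
#' @export
read_record <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path))
    stop(sprintf("record file '%s' not found", path), call. = FALSE)
  if (!file.exists(sidecar))
    stop(sprintf("sidecar '%s' not found; a record needs its paradigm JSON",
                 sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df))
    stop("record CSV is missing column 'time_s'", call. = FALSE)
  nch <- meta$n_channels
  hbo <- matrix(NA_real_, nrow(df), nch)
  hbr <- matrix(NA_real_, nrow(df), nch)
  for (ch in seq_len(nch)) {
    for (kind in c("hbo", "hbr")) {
      col <- sprintf("ch%02d_%s", ch, kind)
      if (!col %in% names(df))
        stop(sprintf("record CSV is missing column '%s'", col),
             call. = FALSE)
    }
    hbo[, ch] <- df[[sprintf("ch%02d_hbo", ch)]]
    hbr[, ch] <- df[[sprintf("ch%02d_hbr", ch)]]
  }
  colnames(hbo) <- colnames(hbr) <- sprintf("ch%02d", seq_len(nch))
  segs <- as.data.frame(meta$segments)
  cfg <- NULL
  stim <- NULL
  if (!is.null(meta$paradigm)) {
    hrf <- if (!is.null(meta$hrf))
      hrf_params(meta$hrf$amplitudes, meta$hrf$shapes, meta$hrf$scales)
      else hrf_params()
    cfg <- synth_config(
      fs = meta$fs, task_s = meta$paradigm$task_s,
      rest_s = meta$paradigm$rest_s, n_trials = meta$paradigm$n_trials,
      n_sessions = meta$paradigm$n_sessions,
      rest_prefix_s = meta$paradigm$rest_prefix_s, n_channels = nch,
      active_channels = if (length(meta$active_channels))
        meta$active_channels else 1L,
      hrf = hrf,
      hrf_duration_s = if (!is.null(meta$hrf)) meta$hrf$duration_s else 30)
    stim <- stimulus_boxcar(meta$fs, cfg$task_s, cfg$rest_s,
                            cfg$n_trials * cfg$n_sessions,
                            lead_rest_s = cfg$rest_prefix_s)
  }
  structure(list(hbo = hbo, hbr = hbr, time_s = df$time_s, fs = meta$fs,
                 segments = segs, stimulus = stim,
                 active_channels = as.integer(meta$active_channels),
                 config = cfg,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed)
                   else NA_integer_),
            class = "fnirs_record")
}
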