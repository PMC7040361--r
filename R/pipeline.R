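#' Pipeline run configuration
#'
#' All defaults equal the settings the predictor and detector are designed
#' around: 9.19 Hz, 2 sessions x 6 trials (10 s task / 20 s rest), 36
#' channels, 0.01-0.15 Hz order-4 causal Butterworth, RLS and
#' Gaussian-kernel KRLS with lambda 0.98, R 1e-8, unit kernel parameters,
#' first-order model, horizons {1, 5, 10, 15, 20}, dip detection on the
#' q = 15 Gaussian-KRLS predictions.
#'
#' @param synth a [synth_config()].
#' @param filter a [filter_spec()].
#' @param models model labels for the fit table.
#' @param qs horizons (samples).
#' @param detect_model,detect_q model/horizon whose predictions feed the
#'   dip detector.
#' @param lambda,R,nu,cap,orders predictor settings (see
#'   [predict_series_q()]).
#' @param candidate_window_s,confirm_after_s,confirm_end_s detector
#'   windows (see [detect_dips()]).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), filter = filter_spec(),
                       models = c("rls", "krls_gaussian"),
                       qs = c(1L, 5L, 10L, 15L, 20L),
                       detect_model = "krls_gaussian", detect_q = 15L,
                       lambda = 0.98, R = 1e-8, nu = 1e-4, cap = 500L,
                       orders = model_orders(),
                       candidate_window_s = 4, confirm_after_s = 2,
                       confirm_end_s = 10, seed = 1L, out_dir = "nirsdip_run") {
  structure(list(synth = synth, filter = filter, models = models,
                 qs = as.integer(qs), detect_model = detect_model,
                 detect_q = as.integer(detect_q), lambda = lambda, R = R,
                 nu = nu, cap = as.integer(cap), orders = orders,
                 candidate_window_s = candidate_window_s,
                 confirm_after_s = confirm_after_s,
                 confirm_end_s = confirm_end_s, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Top-level keys mirror the [run_config()] arguments; nested objects
#' (`synth`, `filter`, `noise`, `hrf`, `orders`) take the corresponding
#' constructor arguments. Missing keys keep their defaults.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(js$synth)) {
    sargs <- js$synth
    if (!is.null(sargs$hrf)) sargs$hrf <- do.call(hrf_params, sargs$hrf)
    if (!is.null(sargs$noise)) sargs$noise <- do.call(noise_params, sargs$noise)
    args$synth <- do.call(synth_config, sargs)
  }
  if (!is.null(js$filter)) args$filter <- do.call(filter_spec, js$filter)
  if (!is.null(js$orders)) args$orders <- do.call(model_orders, js$orders)
  for (key in c("models", "qs", "detect_model", "detect_q", "lambda", "R",
                "nu", "cap", "candidate_window_s", "confirm_after_s",
                "confirm_end_s", "seed", "out_dir"))
    if (!is.null(js[[key]])) args[[key]] <- js[[key]]
  do.call(run_config, args)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full simulate - preprocess - predict - detect pipeline
#'
#' Writes into `config$out_dir`: `record.csv` (+ sidecar), `filtered.csv`
#' (+ sidecar), `fits.tsv` (%FIT per channel/series/model/q),
#' `predictions.csv` (decision-time-aligned predicted HbO/HbR of the
#' detector's model/horizon for the active channels), `dips.tsv`
#' (detection events from measured and predicted trajectories), and
#' `run.log` with resolved parameters, seeds and stage timings.
#'
#' @param config a [run_config()].
#' @param record optional existing `fnirs_record`; when `NULL` a synthetic
#'   one is generated from `config$synth` and `config$seed`.
#' @return Invisibly, a list with `record`, `filtered`, `fits`, `circles`,
#'   `dips`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), record = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  con <- file(logf, "w")
  on.exit(close(con))
  t_all <- proc.time()[["elapsed"]]
  log_line(con, "nirsdip pipeline | seed=%d | out=%s", config$seed,
           config$out_dir)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    log_line(con, "stage %-10s %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  if (is.null(record))
    record <- stage("simulate", generate_dataset(config$synth, config$seed))
  stage("write", write_record(record, file.path(config$out_dir, "record.csv")))
  filtered <- stage("preprocess", {
    f <- bandpass(record, config$filter)
    write_record(f, file.path(config$out_dir, "filtered.csv"))
    f
  })
  fits <- stage("predict", {
    ft <- fit_table(filtered, qs = config$qs, models = config$models,
                    lambda = config$lambda, R = config$R, nu = config$nu,
                    cap = config$cap, orders = config$orders)
    data.table::fwrite(ft, file.path(config$out_dir, "fits.tsv"), sep = "\t")
    ft
  })
  pred <- stage("predict_q", fit_predict_q(
    filtered, config$detect_q, model = config$detect_model,
    channels = record$active_channels, lambda = config$lambda, R = config$R,
    nu = config$nu, cap = config$cap, orders = config$orders))
  circles <- stage("calibrate", calibrate_thresholds(filtered))
  dips <- stage("detect", {
    rows <- list()
    for (i in seq_along(record$active_channels)) {
      ch <- record$active_channels[i]
      for (src in c("measured", "predicted")) {
        if (src == "measured") {
          hbo <- NULL; hbr <- NULL
        } else {
          hbo <- align_to_decision_time(pred$yhat$hbo[, i], config$detect_q)
          hbr <- align_to_decision_time(pred$yhat$hbr[, i], config$detect_q)
        }
        ev <- detect_dips_session(
          filtered, ch, circles, hbo = hbo, hbr = hbr,
          candidate_window_s = config$candidate_window_s,
          confirm_after_s = config$confirm_after_s,
          confirm_end_s = config$confirm_end_s)
        if (nrow(ev)) {
          ev$source <- src
          rows[[length(rows) + 1L]] <- ev
        }
      }
    }
    dips <- if (length(rows)) do.call(rbind, rows) else
      data.frame(channel = integer(0), trial = integer(0),
                 detection_time_s = numeric(0), phase = integer(0),
                 confirmed = logical(0), reason = character(0),
                 hr_time_s = numeric(0), source = character(0))
    dips$detection_time_disp <- truncate_time(dips$detection_time_s)
    data.table::fwrite(dips, file.path(config$out_dir, "dips.tsv"),
                       sep = "\t")
    dips
  })
  # decision-time-aligned predictions of the detector model
  pr <- data.frame(time_s = record$time_s)
  for (i in seq_along(record$active_channels)) {
    ch <- record$active_channels[i]
    pr[[sprintf("ch%02d_hbo", ch)]] <-
      align_to_decision_time(pred$yhat$hbo[, i], config$detect_q)
    pr[[sprintf("ch%02d_hbr", ch)]] <-
      align_to_decision_time(pred$yhat$hbr[, i], config$detect_q)
  }
  data.table::fwrite(pr, file.path(config$out_dir, "predictions.csv"))
  log_line(con, "total %.2f s", proc.time()[["elapsed"]] - t_all)
  invisible(list(record = record, filtered = filtered, fits = fits,
                 circles = circles, dips = dips, out_dir = config$out_dir))
}
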