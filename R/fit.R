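#' Percentage fitting criterion (%FIT)
#'
#' `100 * (1 - SS_res / SS_tot)` with `SS_res = sum((y - yhat)^2)` and
#' `SS_tot = sum((y - mean(y))^2)` (the default, "printed" form). The
#' system-identification convention uses the rooted ratio instead
#' (`type = "nrmse"`: `100 * (1 - sqrt(SS_res / SS_tot))`). Both equal 100
#' for a perfect fit and 0 for the constant-mean predictor; the printed
#' form is the package default and the one reported by the pipeline.
#'
#' @param y measured series (length >= 2, non-constant).
#' @param yhat predicted series, same length.
#' @param type `"printed"` or `"nrmse"`.
#' @return %FIT in percent (<= 100; can be negative for a fit worse than
#'   the mean).
#' @export
percent_fit <- function(y, yhat, type = c("printed", "nrmse")) {
  type <- match.arg(type)
  if (length(y) != length(yhat)) stop("lengths differ", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 samples", call. = FALSE)
  ok <- is.finite(y) & is.finite(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  if (length(y) < 2) stop("need at least 2 finite samples", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("%FIT undefined: measured series has zero variance", call. = FALSE)
  ratio <- sum((y - yhat)^2) / ss_tot
  if (type == "printed") 100 * (1 - ratio) else 100 * (1 - sqrt(ratio))
}

kernel_kind_code <- function(kind) {
  match(kind, c("gaussian", "polynomial", "sigmoid")) - 1L
}

#' Online q-step-ahead prediction of a single series
#'
#' Runs the chosen online estimator over the whole series using the
#' *direct* multi-step strategy: the model for horizon `q` is trained on
#' pairs `(phi(j), y(j + q - 1))`, so the prediction emitted at decision
#' time `k` (when `y(k)` is the newest observation) targets `y(k + q)`.
#' Updates are delayed by `q` samples, keeping the stream strictly causal.
#' The iterated strategy (`strategy = "iterated"`) instead trains a
#' one-step model and feeds predictions back into the output lags `q`
#' times.
#'
#' @param y measured series.
#' @param u input (desired HRF) series on the same grid.
#' @param q prediction horizon in samples (>= 1).
#' @param method `"rls"` or `"krls"`.
#' @param kernel a [kernel_spec()] (KRLS only).
#' @param orders a [model_orders()].
#' @param lambda forgetting factor.
#' @param R KRLS ridge regularizer.
#' @param ald,nu,cap ALD sparsification controls, see [krls_init()].
#' @param p0 RLS initial covariance scale.
#' @param strategy `"direct"` or `"iterated"`.
#' @param engine `"cpp"` (compiled stream) or `"r"` (reference step-by-step
#'   path, direct strategy only).
#' @param w optional exogenous series (needed if `orders$p_o > 0`).
#' @return List with `yhat` (length of `y`, indexed by *target* sample,
#'   `NA` where no prediction exists), `q`, and `dict_size` (KRLS) or
#'   `theta` (RLS).
#' @export
predict_series_q <- function(y, u, q, method = c("rls", "krls"),
                             kernel = kernel_spec(), orders = model_orders(),
                             lambda = 0.98, R = 1e-8, ald = TRUE, nu = 1e-4,
                             cap = 500L, p0 = 1e6,
                             strategy = c("direct", "iterated"),
                             engine = c("cpp", "r"), w = NULL) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  engine <- match.arg(engine)
  stopifnot(q >= 1, length(u) == length(y))
  if (q >= length(y)) stop("`q` must be smaller than the series length",
                           call. = FALSE)
  Phi <- regressor_matrix(y, u, orders, w)
  if (strategy == "iterated")
    return(predict_iterated(y, u, q, method, kernel, orders, lambda, R,
                            ald, nu, cap, p0, w))
  if (engine == "cpp") {
    if (method == "rls") {
      out <- rls_stream_cpp(Phi, y, as.integer(q), lambda, p0)
      yhat <- as.numeric(out$yhat)
      yhat[is.nan(yhat)] <- NA_real_
      list(yhat = yhat, q = q, theta = as.numeric(out$theta))
    } else {
      out <- krls_stream_cpp(Phi, y, as.integer(q),
                             kernel_kind_code(kernel$kind), kernel$sigma,
                             kernel$c, kernel$p, kernel$s, kernel$t,
                             R, lambda, ald, nu, as.integer(cap))
      yhat <- as.numeric(out$yhat)
      yhat[is.nan(yhat)] <- NA_real_
      list(yhat = yhat, q = q, dict_size = out$dict_size)
    }
  } else {
    predict_stream_r(Phi, y, q, method, kernel, lambda, R, ald, nu, cap, p0)
  }
}

# Reference R implementation of the direct-strategy stream; mirrors the
# compiled loop step by step using the exported single-sample updates.
predict_stream_r <- function(Phi, y, q, method, kernel, lambda, R, ald, nu,
                             cap, p0) {
  n <- length(y)
  yhat <- rep(NA_real_, n)
  state <- NULL
  for (j in seq_len(n)) {
    if (j - q >= 1) {
      phi <- Phi[j - q, ]
      target <- y[j - 1]
      if (method == "rls") {
        if (is.null(state)) state <- rls_init(ncol(Phi), lambda, p0)
        state <- rls_update(state, phi, target)$state
      } else {
        if (is.null(state))
          state <- krls_init(phi, target, kernel, R, lambda, ald, nu, cap)
        else state <- krls_update(state, phi, target)$state
      }
    }
    if (j + q - 1 <= n) {
      yhat[j + q - 1] <- if (is.null(state)) 0
      else if (method == "rls") sum(Phi[j, ] * state$theta)
      else krls_predict(state, Phi[j, ])
    }
  }
  res <- list(yhat = yhat, q = q)
  if (method == "krls" && !is.null(state)) res$dict_size <- nrow(state$dict)
  if (method == "rls" && !is.null(state)) res$theta <- state$theta
  res
}

# Iterated strategy: one-step model, predictions fed back into output lags.
predict_iterated <- function(y, u, q, method, kernel, orders, lambda, R,
                             ald, nu, cap, p0, w = NULL) {
  n <- length(y)
  Phi <- regressor_matrix(y, u, orders, w)
  yhat <- rep(NA_real_, n)
  state <- NULL
  predict1 <- function(phi) {
    if (is.null(state)) 0
    else if (method == "rls") sum(phi * state$theta)
    else krls_predict(state, phi)
  }
  n_o <- orders$n_o; m_o <- orders$m_o
  for (k in seq_len(n)) {
    # learn the one-step pair (phi(k), y(k)); both known at time k
    phi <- Phi[k, ]
    if (method == "rls") {
      if (is.null(state)) state <- rls_init(ncol(Phi), lambda, p0)
      state <- rls_update(state, phi, y[k])$state
    } else {
      if (is.null(state))
        state <- krls_init(phi, y[k], kernel, R, lambda, ald, nu, cap)
      else state <- krls_update(state, phi, y[k])$state
    }
    if (k + q > n) next
    # roll the model forward q steps from time k
    hist <- y[seq_len(k)]
    for (step in seq_len(q)) {
      kk <- k + step                # 1-based index being predicted
      lag_y <- if (n_o > 0)
        vapply(seq_len(n_o), function(l) {
          idx <- kk - l
          if (idx >= 1 && idx <= length(hist)) hist[idx] else 0
        }, numeric(1)) else numeric(0)
      lag_u <- if (m_o > 0)
        vapply(seq_len(m_o), function(l) {
          idx <- kk - l
          if (idx >= 1) u[idx] else 0
        }, numeric(1)) else numeric(0)
      ph <- c(lag_y, lag_u, 1)
      hist <- c(hist, predict1(ph))
    }
    yhat[k + q] <- hist[k + q]
  }
  res <- list(yhat = yhat, q = q)
  if (method == "krls" && !is.null(state)) res$dict_size <- nrow(state$dict)
  res
}

model_label <- function(method, kernel) {
  if (method == "rls") "rls" else paste0("krls_", kernel$kind)
}

parse_model <- function(label) {
  if (label == "rls") return(list(method = "rls", kernel = kernel_spec()))
  if (grepl("^krls_", label))
    return(list(method = "krls",
                kernel = kernel_spec(sub("^krls_", "", label))))
  stop(sprintf("unknown model '%s'", label), call. = FALSE)
}

record_input_u <- function(record, hrf = NULL, hrf_duration_s = 30) {
  if (is.null(hrf)) {
    hrf <- if (!is.null(record$config)) record$config$hrf else hrf_params()
    if (!is.null(record$config)) hrf_duration_s <- record$config$hrf_duration_s
  }
  h <- canonical_hrf(hrf, hrf_duration_s, record$fs)
  desired_hrf(h, record$stimulus, normalize = TRUE)$u
}

#' Fit and q-step-ahead predict every channel of a recording
#'
#' Runs [predict_series_q()] on each requested channel and chromophore of
#' a (typically band-pass filtered) recording and scores the predictions
#' with [percent_fit()] on the test segment. Training is online and
#' single-pass; updates continue through the test segment, as they would in
#' a live system.
#'
#' @param record an `fnirs_record`.
#' @param q horizon in samples.
#' @param model model label: `"rls"`, `"krls_gaussian"`,
#'   `"krls_polynomial"`, or `"krls_sigmoid"`.
#' @param test_segment name of the test segment (default `"session2"`);
#'   everything before it is the (online) training stream.
#' @param channels integer channel ids (default: all).
#' @param series which chromophores to fit (default both).
#' @param u model input series; computed from the record's stimulus and HRF
#'   configuration when `NULL`.
#' @param fit_type %FIT variant, see [percent_fit()].
#' @param ... further arguments passed to [predict_series_q()].
#' @return An object of class `prediction_result`: list with `fits` (one
#'   row per channel x series: `channel`, `series`, `model`, `q`, `fit`,
#'   `degenerate`), `yhat` (list of target-indexed prediction matrices per
#'   series), `q`, `model`, `test_idx`.
#' @export
fit_predict_q <- function(record, q, model = "krls_gaussian",
                          test_segment = "session2", channels = NULL,
                          series = c("hbo", "hbr"), u = NULL,
                          fit_type = "printed", ...) {
  stopifnot(inherits(record, "fnirs_record"))
  series <- match.arg(series, several.ok = TRUE)
  if (is.null(channels)) channels <- seq_len(ncol(record$hbo))
  if (is.null(u)) u <- record_input_u(record)
  mdl <- parse_model(model)
  test_idx <- segment_indices(record, test_segment)
  if (q >= length(test_idx)) stop("`q` is not smaller than the test segment",
                                  call. = FALSE)
  fits <- list()
  yhat_out <- lapply(series, function(s)
    matrix(NA_real_, nrow(record$hbo), length(channels),
           dimnames = list(NULL, sprintf("ch%02d", channels))))
  names(yhat_out) <- series
  for (s in series) {
    mat <- record[[s]]
    for (i in seq_along(channels)) {
      ch <- channels[i]
      res <- predict_series_q(mat[, ch], u, q, method = mdl$method,
                              kernel = mdl$kernel, ...)
      yhat_out[[s]][, i] <- res$yhat
      fit <- tryCatch(percent_fit(mat[test_idx, ch], res$yhat[test_idx],
                                  type = fit_type),
                      error = function(e) NA_real_)
      fits[[length(fits) + 1L]] <- data.frame(
        channel = ch, series = s, model = model, q = q, fit = fit,
        degenerate = is.na(fit))
    }
  }
  structure(list(fits = do.call(rbind, fits), yhat = yhat_out, q = q,
                 model = model, test_idx = test_idx),
            class = "prediction_result")
}

#' %FIT table across horizons and models
#'
#' The machine-readable analogue of a multi-horizon comparison table: one
#' row per (channel, series, model, q) with the test-segment %FIT.
#'
#' @param record an `fnirs_record` (filter it first for realistic use).
#' @param qs integer vector of horizons (default `c(1, 5, 10, 15, 20)`).
#' @param models character vector of model labels (see [fit_predict_q()]).
#' @param ... passed to [fit_predict_q()].
#' @return A data.frame of %FIT values.
#' @export
fit_table <- function(record, qs = c(1L, 5L, 10L, 15L, 20L),
                      models = c("rls", "krls_gaussian"), ...) {
  rows <- list()
  for (m in models)
    for (q in qs)
      rows[[length(rows) + 1L]] <- fit_predict_q(record, q, model = m, ...)$fits
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Align target-indexed predictions to decision time
#'
#' `yhat[t]` from [predict_series_q()] is the prediction *of* sample `t`,
#' made `q` samples earlier. For latency analysis the useful indexing is by
#' decision time: the series whose value at sample `k` is the prediction of
#' `y(k + q)` that is available at `k`. Detection run on this series can
#' fire as soon as the *predicted future* enters a dip phase.
#'
#' @param yhat target-indexed prediction vector.
#' @param q horizon in samples.
#' @return Vector of the same length, `NA`-padded at the end.
#' @export
align_to_decision_time <- function(yhat, q) {
  n <- length(yhat)
  stopifnot(q >= 1, q < n)
  c(yhat[(q + 1):n], rep(NA_real_, q))
}
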