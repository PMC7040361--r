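#' Model orders of the brain-activity regression
#'
#' The measured chromophore signal is modeled as an ARX-type regression on
#' its own lags, lags of the desired HRF input `u`, optional lags of an
#' exogenous noise regressor `w`, and a constant. Defaults are first-order
#' output and input with no exogenous term, chosen for low computational
#' cost in online use.
#'
#' @param n_o output (autoregressive) lags (>= 0, default 1).
#' @param m_o input lags (>= 0, default 1).
#' @param p_o exogenous lags (>= 0, default 0).
#' @return An object of class `model_orders`.
#' @export
model_orders <- function(n_o = 1L, m_o = 1L, p_o = 0L) {
  stopifnot(n_o >= 0, m_o >= 0, p_o >= 0)
  structure(list(n_o = as.integer(n_o), m_o = as.integer(m_o),
                 p_o = as.integer(p_o)),
            class = "model_orders")
}

#' Build the regression vector at sample k
#'
#' Returns `[y(k-1) ... y(k-n_o), u(k-1) ... u(k-m_o),
#' w(k-1) ... w(k-p_o), 1]` with zero padding for lags before the start of
#' the series. Indices are zero-based: element `j + 1` of each history
#' vector holds sample `j`, and `k` is the current zero-based sample index.
#'
#' @param y,u numeric histories on the same grid.
#' @param orders a [model_orders()].
#' @param k zero-based current sample index (>= 0).
#' @param w optional exogenous history (required if `orders$p_o > 0`).
#' @return Numeric vector of length `n_o + m_o + p_o + 1`.
#' @export
build_regressor <- function(y, u, orders = model_orders(), k, w = NULL) {
  stopifnot(inherits(orders, "model_orders"), k >= 0)
  if (orders$p_o > 0 && is.null(w))
    stop("`w` history required when p_o > 0", call. = FALSE)
  lag_of <- function(x, lags) {
    idx <- k - lags + 1            # R index of sample (k - lag)
    out <- numeric(length(lags))
    ok <- idx >= 1 & idx <= length(x)
    out[ok] <- x[idx[ok]]
    out
  }
  c(if (orders$n_o > 0) lag_of(y, seq_len(orders$n_o)),
    if (orders$m_o > 0) lag_of(u, seq_len(orders$m_o)),
    if (orders$p_o > 0) lag_of(w, seq_len(orders$p_o)),
    1)
}

# Regressor matrix for a whole series: row j is the regressor at 1-based
# sample j, i.e. [y[j-1], ..., u[j-1], ..., 1] with zero padding.
regressor_matrix <- function(y, u, orders = model_orders(), w = NULL) {
  n <- length(y)
  lagmat <- function(x, l) {
    do.call(cbind, lapply(seq_len(l), function(s) c(numeric(s), x)[seq_len(n)]))
  }
  cols <- list()
  if (orders$n_o > 0) cols <- c(cols, list(lagmat(y, orders$n_o)))
  if (orders$m_o > 0) cols <- c(cols, list(lagmat(u, orders$m_o)))
  if (orders$p_o > 0) cols <- c(cols, list(lagmat(w, orders$p_o)))
  cols <- c(cols, list(matrix(1, n, 1)))
  do.call(cbind, cols)
}

#' Initialize an exponentially weighted RLS estimator
#'
#' Starts from a zero coefficient vector and `P = p0 * I`; a large `p0`
#' encodes an uninformative prior on the coefficients.
#'
#' @param n_params regressor length.
#' @param lambda forgetting factor in (0, 1] (default 0.98).
#' @param p0 initial diagonal of `P` (default 1e6).
#' @return An object of class `rls_state` with fields `theta`, `P`,
#'   `lambda`.
#' @export
rls_init <- function(n_params, lambda = 0.98, p0 = 1e6) {
  stopifnot(n_params >= 1, lambda > 0, lambda <= 1, p0 > 0)
  structure(list(theta = numeric(n_params),
                 P = diag(p0, n_params), lambda = lambda),
            class = "rls_state")
}

#' One exponentially weighted RLS update
#'
#' Standard recursion: gain `g = P phi / (lambda + phi' P phi)`,
#' `theta <- theta + g (y - phi' theta)`,
#' `P <- (P - g phi' P) / lambda`. The returned prediction is the one made
#' *before* the update (the a priori prediction).
#'
#' @param state an `rls_state`.
#' @param phi regressor vector.
#' @param y observed target.
#' @return List with `state`, `prediction`, `error`.
#' @export
rls_update <- function(state, phi, y) {
  stopifnot(inherits(state, "rls_state"))
  phi <- as.numeric(phi)
  if (length(phi) != length(state$theta))
    stop("regressor length does not match state", call. = FALSE)
  assert_finite(c(phi, y), "rls inputs")
  pred <- sum(phi * state$theta)
  err <- y - pred
  Pphi <- drop(state$P %*% phi)
  g <- Pphi / (state$lambda + sum(phi * Pphi))
  state$theta <- state$theta + g * err
  state$P <- (state$P - tcrossprod(g, Pphi)) / state$lambda
  state$P <- (state$P + t(state$P)) / 2   # keep symmetric under round-off
  list(state = state, prediction = pred, error = err)
}
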