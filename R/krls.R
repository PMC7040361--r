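#' Initialize a KRLS estimator from its first sample
#'
#' The dictionary starts with the first regressor; the inverse regularized
#' Gram matrix is `Q(1) = 1 / (R lambda + kappa(phi, phi))` and the dual
#' coefficient is `a(1) = Q(1) y(1)`.
#'
#' @param phi first regressor.
#' @param y first target.
#' @param spec a [kernel_spec()].
#' @param R ridge regularizer (> 0, default 1e-8).
#' @param lambda forgetting factor in (0, 1] (default 0.98); in these
#'   recursions it scales the ridge.
#' @param ald logical, apply the approximate-linear-dependency test
#'   (default `TRUE`).
#' @param nu ALD novelty threshold (>= 0, default 1e-4).
#' @param cap maximum dictionary size (default 500); once reached, updates
#'   no longer grow the dictionary.
#' @return An object of class `krls_state`: `dict` (rows are retained
#'   regressors), `a`, `Q`, `P` (auxiliary matrix of the non-growing ALD
#'   update), and the configuration.
#' @export
krls_init <- function(phi, y, spec = kernel_spec(), R = 1e-8, lambda = 0.98,
                      ald = TRUE, nu = 1e-4, cap = 500L) {
  stopifnot(inherits(spec, "kernel_spec"), R > 0, lambda > 0, lambda <= 1,
            nu >= 0, cap >= 1)
  phi <- as.numeric(phi)
  assert_finite(c(phi, y), "krls inputs")
  k0 <- R * lambda + kernel_eval(spec, phi, phi)
  if (k0 <= 0)
    stop("R*lambda + kappa(phi, phi) must be positive", call. = FALSE)
  q0 <- 1 / k0
  structure(list(dict = matrix(phi, nrow = 1), a = q0 * y,
                 Q = matrix(q0, 1, 1), P = matrix(1, 1, 1),
                 spec = spec, R = R, lambda = lambda, ald = isTRUE(ald),
                 nu = nu, cap = as.integer(cap)),
            class = "krls_state")
}

#' One KRLS update
#'
#' Computes the kernel vector `K(k)` between the new regressor and the
#' dictionary, `z = Q K`, the novelty `delta = R lambda +
#' kappa(phi, phi) - z'K`, and the a priori error `e = y - K'a`. If the
#' sample is novel (`delta > nu`, or ALD disabled) and the dictionary is
#' below its cap, the dictionary grows and `Q`, `a` are extended by the
#' rank-one block recursions; otherwise the dictionary-fixed ALD update
#' adjusts `a` through the auxiliary matrix `P` without growing.
#'
#' @param state a `krls_state`.
#' @param phi new regressor.
#' @param y new target.
#' @return List with `state`, `prediction` (a priori, `K'a`), `error`,
#'   `grown` (logical), `delta`.
#' @export
krls_update <- function(state, phi, y) {
  stopifnot(inherits(state, "krls_state"))
  phi <- as.numeric(phi)
  assert_finite(c(phi, y), "krls inputs")
  K <- kernel_eval(state$spec, state$dict, phi)
  z <- drop(state$Q %*% K)
  delta <- state$R * state$lambda + kernel_eval(state$spec, phi, phi) -
    sum(z * K)
  pred <- sum(K * state$a)
  e <- y - pred
  grow <- (!state$ald || delta > state$nu) && nrow(state$dict) < state$cap
  if (grow) {
    if (delta <= 0)
      stop(sprintf(paste0("numerical degeneracy in KRLS growth: delta = %g",
                          " <= 0 (kernel '%s' may not be positive definite;",
                          " dictionary size %d)"),
                   delta, state$spec$kind, nrow(state$dict)), call. = FALSE)
    m <- nrow(state$dict)
    Qn <- matrix(0, m + 1, m + 1)
    Qn[1:m, 1:m] <- state$Q * delta + tcrossprod(z)
    Qn[1:m, m + 1] <- -z
    Qn[m + 1, 1:m] <- -z
    Qn[m + 1, m + 1] <- 1
    state$Q <- Qn / delta
    state$a <- c(state$a - z * e / delta, e / delta)
    Pn <- diag(1, m + 1)
    Pn[1:m, 1:m] <- state$P
    state$P <- Pn
    state$dict <- rbind(state$dict, phi)
  } else {
    Pz <- drop(state$P %*% z)
    qv <- Pz / (1 + sum(z * Pz))
    state$P <- state$P - tcrossprod(qv, Pz)
    state$a <- state$a + drop(state$Q %*% qv) * e
  }
  list(state = state, prediction = pred, error = e, grown = grow,
       delta = delta)
}

#' Predict with a KRLS state
#'
#' `yhat = sum_j a_j kappa(dict_j, phi)`; a pure function of the state and
#' the query regressor.
#'
#' @param state a `krls_state`.
#' @param phi query regressor.
#' @return Scalar prediction.
#' @export
krls_predict <- function(state, phi) {
  stopifnot(inherits(state, "krls_state"))
  sum(kernel_eval(state$spec, state$dict, as.numeric(phi)) * state$a)
}
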