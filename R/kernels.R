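#' Kernel specification for KRLS
#'
#' Three standard Mercer kernels, with unit defaults for all parameters:
#' Gaussian `exp(-||x - x'||^2 / (2 sigma^2))`, polynomial
#' `(x'y + c)^p`, and sigmoid `tanh(s x'y + t)` (the sigmoid is not
#' positive definite in general; the recursions detect and report the
#' resulting degeneracy if it occurs).
#'
#' @param kind one of `"gaussian"`, `"polynomial"`, `"sigmoid"`.
#' @param sigma Gaussian width (> 0).
#' @param c polynomial offset (>= 0).
#' @param p polynomial degree (integer >= 1).
#' @param s,t sigmoid slope and offset (>= 0).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "polynomial", "sigmoid"),
                        sigma = 1, c = 1, p = 1L, s = 1, t = 1) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && sigma == 0)
    stop("`sigma` must be nonzero", call. = FALSE)
  if (kind == "gaussian" && sigma < 0)
    stop("`sigma` must be > 0", call. = FALSE)
  if (kind == "polynomial" && (c < 0 || p < 1 || p != round(p)))
    stop("polynomial kernel needs c >= 0 and integer p >= 1", call. = FALSE)
  if (kind == "sigmoid" && (s < 0 || t < 0))
    stop("sigmoid kernel needs s >= 0 and t >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, c = c, p = as.integer(p),
                 s = s, t = t),
            class = "kernel_spec")
}

#' Evaluate a kernel
#'
#' `phi1` may be a matrix (one regressor per row), in which case the kernel
#' is evaluated between each row and `phi2`.
#'
#' @param spec a [kernel_spec()].
#' @param phi1 numeric vector, or matrix with `length(phi2)` columns.
#' @param phi2 numeric vector.
#' @return Scalar, or vector of length `nrow(phi1)`.
#' @export
kernel_eval <- function(spec, phi1, phi2) {
  stopifnot(inherits(spec, "kernel_spec"))
  phi2 <- as.numeric(phi2)
  if (is.matrix(phi1)) {
    if (ncol(phi1) != length(phi2))
      stop("regressor lengths differ", call. = FALSE)
    switch(spec$kind,
      gaussian = exp(-rowSums((phi1 - rep(phi2, each = nrow(phi1)))^2) /
                       (2 * spec$sigma^2)),
      polynomial = (drop(phi1 %*% phi2) + spec$c)^spec$p,
      sigmoid = tanh(spec$s * drop(phi1 %*% phi2) + spec$t))
  } else {
    phi1 <- as.numeric(phi1)
    if (length(phi1) != length(phi2))
      stop("regressor lengths differ", call. = FALSE)
    switch(spec$kind,
      gaussian = exp(-sum((phi1 - phi2)^2) / (2 * spec$sigma^2)),
      polynomial = (sum(phi1 * phi2) + spec$c)^spec$p,
      sigmoid = tanh(spec$s * sum(phi1 * phi2) + spec$t))
  }
}
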