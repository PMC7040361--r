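test_that("regressor assembly follows the lag and padding conventions", {
  expect_equal(build_regressor(numeric(0), numeric(0), model_orders(), k = 0),
               c(0, 0, 1))
  expect_equal(build_regressor(5, 2, model_orders(), k = 1), c(5, 2, 1))
  expect_equal(build_regressor(c(1, 2), c(3, 4),
                               model_orders(n_o = 2, m_o = 1), k = 2),
               c(2, 1, 4, 1))
  expect_error(build_regressor(1, 1, model_orders(p_o = 1), k = 1), "`w`")
  # matrix builder row j equals the scalar builder at k = j - 1
  set.seed(1)
  y <- rnorm(8); u <- rnorm(8)
  M <- nirsdip:::regressor_matrix(y, u, model_orders(n_o = 2, m_o = 2))
  for (j in seq_len(8))
    expect_equal(M[j, ], build_regressor(y, u, model_orders(2, 2), k = j - 1))
})

test_that("kernel evaluations match closed forms", {
  g <- kernel_spec("gaussian")
  expect_equal(kernel_eval(g, c(1, 2), c(1, 2)), 1)
  expect_equal(kernel_eval(g, c(1, 0), c(0, 0)), 0.6065306597126334,
               tolerance = 1e-14)
  p <- kernel_spec("polynomial", c = 1, p = 1)
  expect_equal(kernel_eval(p, c(1, 2), c(3, 4)), 12)
  s <- kernel_spec("sigmoid")
  expect_equal(kernel_eval(s, c(1, 0), c(1, 0)), tanh(2))
  # matrix form evaluates row-wise
  expect_equal(kernel_eval(g, rbind(c(1, 0), c(0, 0)), c(0, 0)),
               c(exp(-0.5), 1))
  expect_error(kernel_spec("gaussian", sigma = 0), "sigma")
  expect_error(kernel_eval(g, c(1, 2, 3), c(1, 2)), "lengths")
})

test_that("RLS converges to a constant and recovers a noiseless ARX model", {
  st <- rls_init(1, lambda = 1)
  for (i in 1:100) st <- rls_update(st, 1, 3.5)$state
  expect_equal(unname(st$theta), 3.5, tolerance = 1e-6)
  # noiseless y(k) = 0.5 y(k-1) + u(k-1) + 0.2 with persistent excitation
  set.seed(2)
  n <- 500
  u <- rnorm(n)
  y <- numeric(n)
  for (k in 2:n) y[k] <- 0.5 * y[k - 1] + u[k - 1] + 0.2
  Phi <- nirsdip:::regressor_matrix(y, u, model_orders())
  st <- rls_init(3, lambda = 1)
  for (j in 2:n) st <- rls_update(st, Phi[j, ], y[j])$state
  expect_equal(unname(st$theta), c(0.5, 1, 0.2), tolerance = 1e-6)
  # agrees with batch least squares on the same data
  theta_ls <- qr.solve(Phi[2:n, ], y[2:n])
  expect_equal(unname(st$theta), unname(theta_ls), tolerance = 1e-6)
})

test_that("RLS on an all-zero stream keeps its zero initialization", {
  st <- rls_init(3)
  for (j in 1:20) st <- rls_update(st, c(0, 0, 0), 0)$state
  expect_equal(st$theta, numeric(3))
  expect_error(rls_update(st, c(NA, 0, 0), 1), "finite")
})

test_that("KRLS initialization matches the closed form", {
  st <- krls_init(c(0, 0, 1), y = 2, kernel_spec("gaussian"),
                  R = 1e-8, lambda = 0.98)
  expect_equal(st$a, 2 / (1 + 0.98e-8), tolerance = 1e-14)
  expect_equal(krls_init(c(0, 0, 1), 0, kernel_spec("gaussian"))$a, 0)
  stp <- krls_init(c(0, 0, 1), 1, kernel_spec("polynomial", c = 1, p = 1),
                   R = 1e-8, lambda = 0.98)
  expect_equal(stp$Q[1, 1], 0.5, tolerance = 1e-7)
})

test_that("a repeated regressor is linearly dependent and never grows", {
  phi <- c(0.3, -0.2, 1)
  st <- krls_init(phi, 1, kernel_spec("gaussian"), nu = 1e-4)
  up <- krls_update(st, phi, 1.1)
  expect_false(up$grown)
  expect_equal(nrow(up$state$dict), 1)
  expect_lt(up$delta, 1e-6)
})

test_that("a zero target stream keeps zero coefficients and zero error", {
  set.seed(3)
  st <- krls_init(rnorm(3), 0, kernel_spec("gaussian"))
  for (i in 1:15) {
    up <- krls_update(st, rnorm(3), 0)
    st <- up$state
    expect_equal(up$error, 0)
  }
  expect_equal(st$a, numeric(nrow(st$dict)))
  expect_equal(krls_predict(st, rnorm(3)), 0)
})

test_that("KRLS with ALD off equals batch kernel ridge regression", {
  # sequential predictions on every prefix of a 30-sample stream, all
  # kernels. Small-magnitude regressors keep the sigmoid (tanh) Gram
  # positive definite -- a precondition of the recursion, which reports
  # degeneracy when a non-PSD kernel loses definiteness -- and the ridge
  # is chosen well-conditioned (the recursion/batch identity holds for
  # any R).
  set.seed(4)
  n <- 30
  Phi <- cbind(0.05 * rnorm(n), 0.05 * rnorm(n), 0.05)
  y <- rnorm(n)
  for (kind in c("gaussian", "polynomial", "sigmoid")) {
    spec <- kernel_spec(kind)
    R <- 1e-2; lambda <- 1
    st <- krls_init(Phi[1, ], y[1], spec, R = R, lambda = lambda, ald = FALSE)
    for (j in 2:n) {
      up <- krls_update(st, Phi[j, ], y[j])
      oracle <- krr_predict(spec, Phi[seq_len(j - 1), , drop = FALSE],
                            y[seq_len(j - 1)], Phi[j, ], ridge = R * lambda)
      expect_equal(up$prediction, oracle, tolerance = 1e-8,
                   info = paste(kind, "prefix", j))
      st <- up$state
    }
  }
})

test_that("predictions far from a Gaussian dictionary decay to zero", {
  set.seed(5)
  st <- krls_init(c(0, 0, 1), 2, kernel_spec("gaussian"))
  for (j in 1:5) st <- krls_update(st, rnorm(3), rnorm(1))$state
  far <- c(100, 100, 1)
  expect_lt(abs(krls_predict(st, far)), 1e-6 * sum(abs(st$a)))
})

test_that("percent fit: worked values and degenerate input", {
  y <- c(1, 2, 3)
  expect_equal(percent_fit(y, y), 100)
  expect_equal(percent_fit(y, rep(mean(y), 3)), 0)
  expect_equal(percent_fit(y, c(1, 2, 4)), 50)
  expect_equal(percent_fit(y, c(1, 2, 4), type = "nrmse"),
               100 * (1 - sqrt(0.5)))
  expect_error(percent_fit(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(percent_fit(1:3, 1:4), "lengths")
})
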