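test_that("the penalty follows its three branches", {
  expect_equal(scadPenalty(0, 1, 3.7), 0)
  expect_equal(scadPenalty(0.5, 1, 3.7), 0.5)                 # linear branch
  expect_equal(scadPenalty(2, 1, 3.7), -(4 - 14.8 + 1) / 5.4) # clipped branch
  expect_equal(scadPenalty(5, 1, 3.7), 4.7 / 2)               # plateau
  expect_equal(scadPenalty(-2, 1, 3.7), scadPenalty(2, 1, 3.7))
  expect_error(scadPenalty(1, 1, 2), "gamma")
  expect_error(scadPenalty(1, 0), "lambda")
})

test_that("orthonormal-design solutions match the 1-D brute-force oracle", {
  X <- orthonormalDesign()
  set.seed(3)
  for (lam in c(0.15, 0.6, 1.4)) {
    for (rep in 1:5) {
      y <- drop(X %*% runif(2, -3, 3)) + rnorm(8, 0, 0.3)
      y <- y - mean(y)
      fit <- scadFit(y, X, lambdaStrategy = "fixed", lambda = lam)
      z <- drop(crossprod(X, y)) / 8
      oracle <- vapply(z, scadOracle1d, numeric(1),
                       lambda = lam, gamma = 3.7)
      expect_equal(unname(fit@beta), unname(oracle), tolerance = 1e-6)
    }
  }
})

test_that("a proportional column recovers the least-squares slope", {
  set.seed(4)
  x <- hweMatrix(40, 1)
  y <- 2.5 * x[, 1]
  fit <- scadFit(y, x, lambdaStrategy = "fixed", lambda = 1e-4)
  expect_equal(fit@nonzero, 1L)
  expect_equal(fit@beta[1], 2.5, tolerance = 1e-6)
})

test_that("extreme penalties give the null and least-squares limits", {
  set.seed(6)
  X <- hweMatrix(50, 3)
  b <- c(1.5, -0.8, 0)
  y <- drop(X %*% b) + rnorm(50, 0, 0.5)
  atMax <- scadFit(y, X, lambdaStrategy = "fixed", lambda = 50)
  expect_equal(atMax@beta, numeric(3))
  ols <- qr.coef(qr(cbind(1, X)), y)[-1]
  near0 <- scadFit(y, X, lambdaStrategy = "fixed", lambda = 1e-6)
  expect_equal(unname(near0@beta), unname(ols), tolerance = 1e-4)
})

test_that("pure noise gives the all-zero fit under the default path", {
  set.seed(8)
  X <- hweMatrix(80, 30)
  y <- rnorm(80)
  fit <- scadFit(y, X)
  expect_lte(length(fit@nonzero), 1)
})

test_that("the objective is non-increasing across sweeps and self-consistent", {
  set.seed(10)
  X <- hweMatrix(60, 20)
  y <- drop(X[, 1:3] %*% c(2, -1.5, 1)) + rnorm(60)
  fit <- scadFit(y, X, lambdaStrategy = "fixed", lambda = 0.2, trace = TRUE)
  tr <- attr(fit, "objectiveTrace")
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-10))
  expect_equal(scadObjective(fit, y, X), fit@objective, tolerance = 1e-8)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(scadFit(c(1), cbind(1)), "two observations")
  expect_error(scadFit(rnorm(10), hweMatrix(10, 2), gamma = 1.5), "gamma")
  # constant response: nothing to fit
  fit <- scadFit(rep(3, 12), hweMatrix(12, 4))
  expect_equal(fit@beta, numeric(4))
  expect_equal(fit@intercept, 3)
})
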