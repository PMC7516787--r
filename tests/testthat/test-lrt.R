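test_that("LOD scoring follows the log10 likelihood-ratio definition", {
  expect_equal(lodScore(-5, -5), 0)
  expect_equal(lodScore(0, 6.9078), 3, tolerance = 1e-4)
  expect_equal(lodScore(0, 2.3026), 1, tolerance = 1e-4)
  expect_warning(clamped <- lodScore(1, 0.5), "clamping")
  expect_equal(clamped, 0)
  expect_error(lodScore(NA, 1), "finite")
})

test_that("one-marker LOD equals the explicit two-OLS-fit oracle", {
  set.seed(61)
  X <- hweMatrix(120, 1)
  y <- 1.8 * X[, 1] + rnorm(120, 0, 2)
  res <- testMarker(y, X, 1)
  oracle <- 2 * (olsLogLikOracle(y, X) - olsLogLikOracle(y)) / (2 * log(10))
  expect_equal(res$lod, oracle, tolerance = 1e-10)
  expect_equal(res$pValue,
               pchisq(2 * (olsLogLikOracle(y, X) - olsLogLikOracle(y)),
                      1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("an orthogonal marker contributes no likelihood", {
  set.seed(62)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- qr.resid(qr(cbind(1, x1)), x2)      # orthogonal to x1 and intercept
  e <- qr.resid(qr(cbind(1, x1, x2)), rnorm(n))
  y <- 2 * x1 + e                           # y carries nothing along x2
  res <- testMarker(y, cbind(x1, x2), 2)
  expect_lt(res$lod, 1e-8)
})

test_that("nuisance effects are refit under the null (nested test)", {
  set.seed(63)
  X <- hweMatrix(100, 3)
  y <- 2 * X[, 1] + 1.5 * X[, 2] + rnorm(100)
  res <- testMarker(y, X, 3)
  # oracle: both models refit all remaining effects
  l1 <- olsLogLikOracle(y, X)
  l0 <- olsLogLikOracle(y, X[, 1:2])
  expect_equal(res$lod, 2 * (l1 - l0) / (2 * log(10)), tolerance = 1e-10)
})

test_that("singular retained designs fall back to a ridge refit", {
  set.seed(64)
  x <- hweMatrix(30, 1)
  X <- cbind(x, x)  # duplicated marker
  y <- 2 * x[, 1] + rnorm(30)
  expect_warning(res <- testMarker(y, X, 1), "singular|ridge")
  expect_true(is.finite(res$lod))
})

test_that("significance is re-called at exact LOD thresholds", {
  tab <- data.frame(snp_id = c("a", "b", "c"), chrom = 1L, pos = 1:3,
                    effect = c(1, 1, 1), lod = c(3.0, 2.999, 5),
                    p_value = c(2e-4, 3e-4, 1e-6),
                    significant = c(TRUE, FALSE, TRUE))
  res <- new("AssociationResult", table = tab, threshold = 3)
  expect_equal(associationTable(res)$significant, c(TRUE, FALSE, TRUE))
  at3 <- callSignificant(res, 3)
  expect_equal(associationTable(at3)$significant, c(TRUE, FALSE, TRUE))
  at2 <- callSignificant(res, 2)
  expect_equal(associationTable(at2)$significant, c(TRUE, TRUE, TRUE))
  # the looser call set is a superset
  expect_true(all(which(associationTable(at3)$significant) %in%
                  which(associationTable(at2)$significant)))
})
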