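test_that("entropy matches the closed forms", {
  expect_equal(entropyNats(1), 0)
  expect_equal(entropyNats(c(0.5, 0.5)), log(2))
  expect_equal(entropyNats(rep(1 / 3, 3)), log(3))
  expect_equal(entropyNats(c(1, 0)), 0)   # 0 log 0 convention
  expect_error(entropyNats(c(-0.1, 1.1)), "non-negative")
  expect_error(entropyNats(c(0.3, 0.3)), "sum to 1")
})

test_that("mutual information matches hand-computable joints", {
  # product joint: independent
  expect_equal(mutualInformation(outer(c(2, 3), c(1, 4))), 0, tolerance = 1e-12)
  # deterministic copy, uniform on 3 states
  expect_equal(mutualInformation(diag(3)), log(3))
  # counts [[2,0],[0,2]]: I = ln 2
  expect_equal(mutualInformation(rbind(c(2, 0), c(0, 2))), log(2))
})

test_that("the entropy and direct-sum routes agree to 1e-10", {
  set.seed(21)
  for (i in 1:100) {
    tab <- randomJointTable()
    expect_equal(mutualInformation(tab, "entropy"),
                 mutualInformation(tab, "direct"), tolerance = 1e-10)
  }
})

test_that("MI is bounded, non-negative and symmetric", {
  set.seed(22)
  for (i in 1:50) {
    tab <- randomJointTable(3, 5)
    p <- tab / sum(tab)
    I <- mutualInformation(tab)
    expect_gte(I, -1e-12)
    expect_lte(I, min(entropyNats(rowSums(p)), entropyNats(colSums(p))) + 1e-12)
    expect_equal(I, mutualInformation(t(tab)), tolerance = 1e-12)
  }
})

test_that("SNP-phenotype MI handles the spec'd special cases", {
  # constant genotype: no information
  expect_equal(snpPhenotypeMI(rep(1, 30), rnorm(30)), 0)
  # constant phenotype: 0 with warning
  expect_warning(out <- snpPhenotypeMI(hweMatrix(30, 1)[, 1], rep(2, 30)),
                 "constant")
  expect_equal(out, 0)
  # strictly monotone map of 3 equally frequent states: ln(3)
  x <- rep(c(-1, 0, 1), each = 10)
  y <- 2 * x + 5
  expect_equal(snpPhenotypeMI(x, y, bins = 3), log(3))
})

test_that("permuting the phenotype destroys association information", {
  set.seed(23)
  x <- hweMatrix(600, 1)[, 1]
  y <- 1.5 * x + rnorm(600)
  miTrue <- snpPhenotypeMI(x, y)
  miPerm <- snpPhenotypeMI(x, sample(y))
  expect_gt(miTrue, miPerm)
})

test_that("panel-wide MI scores equal the per-SNP computation", {
  set.seed(24)
  X <- hweMatrix(80, 12, f = 0.4)
  y <- rnorm(80) + X[, 3]
  scores <- miScores(X, y, bins = 9)
  each <- vapply(seq_len(12), function(j) snpPhenotypeMI(X[, j], y, bins = 9),
                 numeric(1))
  expect_equal(scores, each, tolerance = 1e-12)
})

test_that("joint tables validate their invariants", {
  jd <- jointDistribution(c(-1, 0, 1, 1), c(1, 2, 3, 4), bins = 2)
  expect_equal(jd@nObs, 4)
  expect_equal(sum(jd@counts), 4)
  expect_error(new("JointDistribution", counts = rbind(c(-1, 2)), nObs = 1),
               "non-negative")
})
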