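test_that("Pearson scores match the hand-computed correlation", {
  x <- c(1, 1, -1, -1)
  y <- c(3, 1, 1, -1)
  expect_equal(pearsonScores(cbind(x), y)[1], sqrt(0.5), tolerance = 1e-9)
  expect_equal(pearsonScores(cbind(2 * y + 3), y)[1], 1)
  expect_equal(pearsonScores(cbind(-y), y)[1], -1)
  expect_warning(w <- pearsonScores(cbind(x, rep(1, 4)), y), "constant SNP")
  expect_equal(w[2], 0)
  expect_error(pearsonScores(cbind(x), rep(2, 4)), "constant phenotype")
})

test_that("top selection keeps cutoff ties and degenerate panels", {
  expect_equal(topSelect(c(.9, .5, .4, .3, .1), 3), 1:3)
  expect_equal(topSelect(c(.9, .5, .5, .5, .1), 3), 1:4)  # tie inclusion
  expect_warning(all5 <- topSelect(c(.2, .1, .3), 5), "keeping all")
  expect_equal(all5, 1:3)
  # Pearson ranks by magnitude, MI by raw value
  expect_equal(topSelect(c(-.9, .5, .1), 2, useAbsolute = TRUE), 1:2)
  expect_equal(topSelect(c(-.9, .5, .1), 2, useAbsolute = FALSE), 2:3)
})

test_that("SIS-SCAD finds a strong QTN among null SNPs", {
  set.seed(31)
  X <- hweMatrix(200, 1000)
  tr <- singleQtnTrait(X, qtn = 417, h2 = 0.3)
  out <- sisScad(X, tr$y, "pearson")
  expect_true(417 %in% out$typeI)
  outMi <- sisScad(X, tr$y, "mi")
  expect_true(417 %in% outMi$typeI)
})

test_that("screening a pure-noise panel selects little or nothing", {
  set.seed(32)
  X <- hweMatrix(100, 300)
  y <- rnorm(100)
  out <- sisScad(X, y, "pearson")
  expect_lte(length(out$typeI), 2)
})

test_that("one ISIS iteration revives a masked predictor", {
  set.seed(33)
  n <- 150; p <- 400
  X <- hweMatrix(n, p)
  # make column 2 strongly correlated with column 1
  copy <- rbinom(n, 1, 0.85) == 1
  X[copy, 2] <- X[copy, 1]
  r <- cor(X[, 1], X[, 2])
  # choose the masked effect so the marginal correlation of column 2 vanishes
  b1 <- 3
  b2 <- -b1 * r
  y <- b1 * X[, 1] + b2 * X[, 2] + rnorm(n, 0, 0.7)
  first <- sisScad(X, y, "pearson")
  expect_true(1 %in% first$typeI)
  expect_false(2 %in% first$typeI)
  typeII <- isisIteration(X, y, first$typeI, first$fit, "pearson")
  expect_true(2 %in% typeII)
  expect_length(intersect(first$typeI, typeII), 0)
})

test_that("ISIS degenerates gracefully", {
  set.seed(34)
  X <- hweMatrix(60, 20)
  y <- rnorm(60)
  # empty type I: the rerun is plain SIS-SCAD on everything (the panel is
  # smaller than the screening size, which is itself worth a warning)
  fit0 <- scadFit(y, X, lambdaStrategy = "fixed", lambda = 100)
  expect_warning(t2 <- isisIteration(X, y, integer(0), fit0, "pearson"),
                 "keeping all")
  expect_equal(sort(t2),
               sort(suppressWarnings(sisScad(X, y, "pearson"))$typeI))
  # type I covering all SNPs: nothing left to screen
  fitAll <- scadFit(y, X, lambdaStrategy = "fixed", lambda = 1e-6)
  names(fitAll@beta) <- as.character(seq_len(20))
  expect_equal(isisIteration(X, y, 1:20, fitAll, "pearson"), integer(0))
})

test_that("screening is invariant to positive affine phenotype rescaling", {
  set.seed(35)
  X <- hweMatrix(120, 250)
  tr <- singleQtnTrait(X, qtn = 42, h2 = 0.25)
  a <- screenPanel(X, tr$y, "pearson")
  b <- screenPanel(X, 3.2 * tr$y + 7, "pearson")
  expect_equal(screenScores(a), screenScores(b), tolerance = 1e-12)
  expect_equal(typeISet(a), typeISet(b))
  expect_equal(typeIISet(a), typeIISet(b))
})

test_that("type sets stay disjoint across seeds and measures", {
  for (s in 1:5) {
    set.seed(40 + s)
    X <- hweMatrix(80, 150)
    y <- rnorm(80) + X[, 7] * 1.2
    for (ms in c("pearson", "mi")) {
      sr <- screenPanel(X, y, ms)
      expect_length(intersect(typeISet(sr), typeIISet(sr)), 0)
      expect_equal(length(unionSet(sr)),
                   length(typeISet(sr)) + length(typeIISet(sr)))
    }
  }
})

test_that("candidate union de-duplicates and reports overlap", {
  u <- unionCandidates(c(1L, 2L), c(2L, 3L))
  expect_equal(u$candidates, 1:3)
  expect_equal(u$overlap, 1 / 3)
  expect_equal(unionCandidates(c(1L, 2L), c(3L, 4L))$candidates, 1:4)
  same <- unionCandidates(c(5L, 9L), c(9L, 5L))
  expect_equal(same$candidates, c(5L, 9L))
  expect_equal(same$overlap, 1)
})

test_that("a null panel keeps the mean candidate set well below n", {
  set.seed(44)
  n <- 100
  sizes <- vapply(1:20, function(i) {
    X <- hweMatrix(n, 300)
    y <- rnorm(n)
    a <- screenPanel(X, y, "pearson")
    b <- screenPanel(X, y, "mi")
    length(unionCandidates(a, b)$candidates)
  }, numeric(1))
  expect_lt(mean(sizes), n / 2)
})
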