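# helpers to fabricate results/truths with controlled coordinates
fakeResult <- function(pos, lod = 5, chrom = 1L, effect = 1) {
  n <- length(pos)
  tab <- data.frame(snp_id = sprintf("s%02d", seq_len(n)),
                    chrom = rep_len(chrom, n), pos = pos,
                    effect = rep_len(effect, n), lod = rep_len(lod, n),
                    p_value = rep_len(1e-5, n),
                    significant = rep_len(lod, n) >= 3)
  new("AssociationResult", table = tab, threshold = 3)
}
fakeTruth <- function(pos, chrom = 1L, effects = NULL) {
  m <- length(pos)
  if (is.null(effects)) effects <- rep(2, m)
  simTruth(seq_len(m), effects, rep(0.4 / m, m) + 0.01,
           qtnChrom = rep_len(chrom, m), qtnPos = pos)
}

test_that("the 1 kb matching rule is a sharp boundary", {
  truth <- fakeTruth(10000)
  expect_true(matchQtns(fakeResult(10000), truth)$detected)   # exact position
  expect_true(matchQtns(fakeResult(10999), truth)$detected)   # 999 bp away
  expect_true(matchQtns(fakeResult(11000), truth)$detected)   # boundary
  m <- matchQtns(fakeResult(11001), truth)                    # 1001 bp away
  expect_false(m$detected)
  expect_equal(m$nFalsePositives, 1L)
  # wrong chromosome never matches
  expect_false(matchQtns(fakeResult(10000, chrom = 2L), truth)$detected)
})

test_that("each significant SNP matches at most its nearest QTN", {
  truth <- fakeTruth(c(10000, 10800))
  m <- matchQtns(fakeResult(c(10050, 10790)), truth)
  expect_equal(m$matches, c(1L, 2L))
  expect_true(all(m$detected))
  expect_equal(m$nFalsePositives, 0L)
  # no significant SNPs: nothing detected, nothing false
  none <- matchQtns(fakeResult(numeric(0)), truth)
  expect_false(any(none$detected))
  expect_equal(none$nFalsePositives, 0L)
})

test_that("power is the detection frequency with an SD robustness summary", {
  det <- matrix(FALSE, 1000, 2)
  det[seq_len(724), 1] <- TRUE
  pw <- powerPerQtn(det)
  expect_equal(pw$power, c(0.724, 0))
  expect_equal(powerPerQtn(rbind(c(TRUE, TRUE), c(TRUE, TRUE)))$sd, 0)
  pw2 <- powerPerQtn(rbind(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE)),
                     sdSubset = 2:3)
  expect_equal(pw2$sd, sd(c(0.5, 1)))
})

test_that("MSE follows its definition with both undetected conventions", {
  expect_equal(msePerQtn(cbind(c(2, 2)), 2)$mse, 0)
  expect_equal(msePerQtn(cbind(c(3, 3)), 2)$mse, 1)
  expect_equal(msePerQtn(cbind(c(2.1, 1.7)), 2)$mse, 0.05)
  est <- cbind(c(2.5, NA))
  expect_equal(msePerQtn(est, 2, "omit")$mse, 0.25)
  expect_equal(msePerQtn(est, 2, "zero")$mse, (0.25 + 4) / 2)
  expect_equal(msePerQtn(est, 2)$nDetected, 1L)
})

test_that("the type-1 ratio is false positives over null tests, in percent", {
  expect_equal(type1ErrorRatio(0L, 10000), 0)
  expect_equal(type1ErrorRatio(3L, 10000), 0.03)
  expect_equal(type1ErrorRatio(c(10000L), 10000), 100)
  expect_equal(type1ErrorRatio(c(1L, 2L), c(5000, 5000)), 0.03)
})

test_that("null-SNP counting excludes the QTN windows", {
  map <- data.frame(snp_id = sprintf("s%d", 1:5), chrom = 1L,
                    pos = c(1000, 10500, 11000, 12050, 50000))
  truth <- fakeTruth(11000)
  expect_equal(countNullSnps(map, truth), 3L)   # 10500 and 11000 excluded
  expect_equal(countNullSnps(map, truth, window = 10), 4L)
})

test_that("loosening the LOD threshold never loses power, never false calls", {
  truth <- fakeTruth(c(10000, 40000))
  pos <- c(10100, 40200, 70000, 90000)
  res <- fakeResult(pos, lod = c(5, 2.5, 2.2, 4))
  strict <- matchQtns(callSignificant(res, 3), truth)
  loose <- matchQtns(callSignificant(res, 2), truth)
  expect_true(all(loose$detected >= strict$detected))
  expect_gte(loose$nFalsePositives, strict$nFalsePositives)
})
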