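test_that("genotype simulation is reproducible and honours frequencies", {
  G1 <- simulateGenotypes(50, 30, seed = 71)
  G2 <- simulateGenotypes(50, 30, seed = 71)
  expect_identical(genotypes(G1), genotypes(G2))
  expect_identical(snpMap(G1), snpMap(G2))
  # empirical allele frequencies track the target within binomial noise
  f <- rep(0.5, 40)
  G <- simulateGenotypes(600, 40, mafSpec = f, seed = 72)
  fhat <- alleleFrequencies(G)
  sdf <- sqrt(0.5 * 0.5 / (2 * 600))
  expect_lt(max(abs(fhat - 0.5)), 5 * sdf)
  expect_error(simulateGenotypes(10, 5, mafSpec = c(0, 0.6)), "range")
})

test_that("the synthetic map is ordered and chromosome-partitioned", {
  G <- simulateGenotypes(10, 100, nChrom = 5, seed = 73)
  map <- snpMap(G)
  expect_equal(sort(unique(map$chrom)), 1:5)
  for (ch in 1:5)
    expect_true(all(diff(map$pos[map$chrom == ch]) > 0))
})

test_that("block LD induces adjacent correlation; independence does not", {
  G0 <- simulateGenotypes(400, 30, ldRho = 0, seed = 74)
  X0 <- genotypes(G0)
  r0 <- mean(abs(vapply(1:29, function(j) cor(X0[, j], X0[, j + 1]),
                        numeric(1))))
  G9 <- simulateGenotypes(400, 30, ldRho = 0.9, seed = 74)
  X9 <- genotypes(G9)
  r9 <- mean(vapply(1:29, function(j) cor(X9[, j], X9[, j + 1]), numeric(1)))
  expect_lt(r0, 0.15)
  expect_gt(r9, 0.4)
})

test_that("variance accounting reproduces the scenario budgets", {
  h <- c(0.10, 0.05, 0.05, 0.15, 0.05, 0.05)
  # additive-only: VP = 10 / 0.55
  b <- effectsFromHeritability(h, rep(0.3, 6), sigma2e = 10)
  expect_equal(attr(b, "budget")$VP, 10 / 0.55, tolerance = 1e-12)
  expect_equal(b[1], sqrt(0.1 * (10 / 0.55) / 0.42), tolerance = 1e-12)
  # polygenic scenario: implied h2pg = 2 / (12 / 0.55)
  bud2 <- varianceBudget(h, 10, sigma2pg = 2)
  expect_equal(bud2$VP, 12 / 0.55, tolerance = 1e-12)
  expect_equal(bud2$h2pg, 2 / (12 / 0.55), tolerance = 1e-12)
  # epistatic scenario: three pairs at 1.25 each -> per-pair h2 = 0.05
  bud3 <- varianceBudget(h, 10, sigma2epiPerPair = rep(1.25, 3))
  expect_equal(bud3$VP, 25, tolerance = 1e-12)
  expect_equal(bud3$h2epiPerPair, rep(0.05, 3), tolerance = 1e-12)
  expect_error(effectsFromHeritability(c(0.6, 0.5), c(0.3, 0.3), 10),
               "less than 1")
})

test_that("a no-QTN draw has the stated mean and residual variance", {
  set.seed(75)
  G <- simulateGenotypes(8000, 3, seed = 75)
  truth <- simTruth(1L, 0, 1e-9, mu = 10, sigma2e = 10,
                    qtnChrom = 1L, qtnPos = 1)
  y <- simulatePhenotype(G, truth, scenario = 1)
  expect_lt(abs(mean(y) - 10), 3 * sqrt(10 / 8000))
  expect_lt(abs(var(y) - 10), 3 * sqrt(2 / 8000) * 10)
})

test_that("simulated QTNs realize their target heritabilities", {
  sim <- simulateScenario(1, n = 8000, p = 40, seed = 76)
  X <- genotypes(sim$genotypes)
  tr <- sim$truth
  vy <- var(as.numeric(sim$phenotype))
  h4 <- var(X[, tr@qtnIndices[4]]) * tr@qtnEffects[4]^2 / vy
  expect_lt(abs(h4 - 0.15), 0.02)
  expect_lt(abs(vy - 10 / 0.55), 1.5)
})

test_that("kinship is a symmetric PSD relatedness matrix", {
  set.seed(77)
  X <- hweMatrix(30, 3000)
  K <- kinshipMatrix(X)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # unrelated individuals: off-diagonals near zero
  expect_lt(max(abs(K[upper.tri(K)])), 0.15)
  # duplicated individuals share their kinship row
  X2 <- rbind(X[1, ], X)
  K2 <- kinshipMatrix(X2)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_warning(kinshipMatrix(cbind(X, rep(1, 30))), "zero-variance")
})

test_that("the polygenic term follows the kinship covariance", {
  sim <- simulateScenario(2, n = 40, p = 300, sigma2pg = 10, seed = 78)
  tr <- sim$truth
  G <- sim$genotypes
  # many redraws of the same architecture: cov(y) ~ sigma2pg K + sigma2e I
  set.seed(79)
  Y <- replicate(1500, as.numeric(simulatePhenotype(G, tr, scenario = 2)))
  empCov <- cov(t(Y))
  off <- upper.tri(empCov)
  expect_gt(cor(empCov[off], tr@kinship[off]), 0.5)
  expect_gt(var(as.numeric(Y)), var(as.numeric(
    replicate(50, as.numeric(simulatePhenotype(G, tr, scenario = 1))))))
})

test_that("epistatic scenarios enforce locus separation and add variance", {
  expect_error(simTruth(c(1L, 2L), c(1, 1), c(0.1, 0.1),
                        epistaticPairs = cbind(a = 2, b = 5, effect = 1),
                        qtnChrom = c(1L, 1L), qtnPos = c(1, 2)),
               "distinct")
  sim <- simulateScenario(3, n = 300, p = 100, seed = 80)
  ep <- sim$truth@epistaticPairs
  expect_equal(nrow(ep), 3)
  expect_length(intersect(c(ep[, 1], ep[, 2]), sim$truth@qtnIndices), 0)
  # per-pair variance contribution tracks its budget (sigma2epi = 1.25)
  X <- genotypes(sim$genotypes)
  vpair <- var(X[, ep[1, 1]] * X[, ep[1, 2]]) * ep[1, 3]^2
  expect_lt(abs(vpair - 1.25), 0.45)
})

test_that("truth JSON round-trips (kinship excepted)", {
  sim <- simulateScenario(3, n = 30, p = 60, seed = 81)
  f <- tempfile(fileext = ".json")
  writeSimTruth(sim$truth, f)
  back <- readSimTruth(f)
  expect_equal(back@qtnIndices, sim$truth@qtnIndices)
  expect_equal(back@qtnEffects, sim$truth@qtnEffects, tolerance = 1e-12)
  expect_equal(back@epistaticPairs, sim$truth@epistaticPairs,
               tolerance = 1e-12)
  expect_equal(back@qtnPos, sim$truth@qtnPos)
})
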