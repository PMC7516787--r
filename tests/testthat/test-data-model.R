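test_that("validateGenotypes accepts coded matrices and fills dimensions", {
  G <- validateGenotypes(rbind(c(1, 0), c(-1, 1)),
                         data.frame(snp_id = c("a", "b"), chrom = 1:2,
                                    pos = c(100, 200)))
  expect_s4_class(G, "GenotypeMatrix")
  expect_equal(nIndividuals(G), 2)
  expect_equal(nSnps(G), 2)
  expect_equal(dim(G), c(2L, 2L))
})

test_that("coding violations are rejected with row/column coordinates", {
  m <- rbind(c(1, 0), c(2, -1))
  expect_error(validateGenotypes(m), "row 2, column 1")
  expect_error(validateGenotypes(rbind(c(1, 0.5), c(0, 0))), "column 2")
})

test_that("map/panel mismatches are structural errors", {
  m <- rbind(c(1, 0), c(-1, 1))
  badMap <- data.frame(snp_id = c("a", "b", "c"), chrom = 1, pos = 1:3)
  expect_error(validateGenotypes(m, badMap), "3 rows")
  dupMap <- data.frame(snp_id = c("a", "b"), chrom = 1, pos = c(5, 5))
  expect_error(validateGenotypes(m, dupMap), "unique")
})

test_that("missing calls are rejected unless mode imputation is requested", {
  m <- rbind(c(1, NA), c(-1, 0), c(1, 0))
  expect_error(validateGenotypes(m), "missing")
  G <- validateGenotypes(m, impute = TRUE)
  expect_equal(genotypes(G)[1, 2], 0)  # column mode of (0, 0)
  # tie between -1 and 1 resolves toward the heterozygote preference order
  m2 <- cbind(c(NA, -1, 1, -1, 1))
  expect_equal(imputeMode(m2)[1, 1], -1)
})

test_that("subsetting keeps the map in step with the columns", {
  G <- validateGenotypes(hweMatrix(10, 5))
  sub <- G[1:4, c(2, 5)]
  expect_equal(dim(sub), c(4L, 2L))
  expect_equal(snpMap(sub)$snp_id, snpMap(G)$snp_id[c(2, 5)])
})

test_that("genotype text round-trip is the identity", {
  set.seed(11)
  G <- simulateGenotypes(12, 8, seed = 11)
  gf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeGenotypes(G, gf, mf)
  G2 <- readGenotypes(gf, mf)
  expect_equal(unname(genotypes(G2)), unname(genotypes(G)))
  expect_equal(snpMap(G2), snpMap(G))
})

test_that("phenotype and covariate readers tolerate comments and NA", {
  pf <- tempfile()
  writeLines(c("# trait file", "id\tvalue", "i1\t1.5", "i2\tNA", "i3\t2.5"),
             pf)
  y <- readPhenotype(pf)
  expect_equal(unname(y), c(1.5, NA, 2.5))
  expect_equal(names(y), c("i1", "i2", "i3"))
  qf <- tempfile()
  writeLines(c("# covariates", "q1\tq2", "0.1\t0.9", "0.4\t0.6", "0.5\t0.5"),
             qf)
  Q <- readCovariates(qf)
  expect_equal(dim(Q@Q), c(3L, 2L))
})

test_that("PLINK .raw dosages are recoded to the additive convention", {
  rf <- tempfile()
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
               "f1 i1 0 0 1 -9 2 1",
               "f2 i2 0 0 2 -9 0 1"), rf)
  G <- readPlinkRaw(rf)
  expect_equal(unname(genotypes(G)), rbind(c(1, 0), c(-1, 0)))
  expect_equal(snpMap(G)$snp_id, c("rs1", "rs2"))
})

test_that("screening and association tables serialize to delimited text", {
  sr <- new("ScreenResult", scores = c(0.9, 0.1, 0.5),
            typeI = 1L, typeII = 3L, measure = "pearson")
  map <- data.frame(snp_id = c("a", "b", "c"), chrom = 1, pos = 1:3)
  f <- tempfile()
  tab <- writeScreenResult(sr, map, f)
  expect_equal(tab$type, c("I", "-", "II"))
  back <- read.table(f, header = TRUE, stringsAsFactors = FALSE)
  expect_equal(back$selected, c(TRUE, FALSE, TRUE))
})

test_that("ScreenResult enforces disjoint type sets", {
  expect_error(new("ScreenResult", scores = c(1, 2, 3), typeI = c(1L, 2L),
                   typeII = 2L, measure = "pearson"), "disjoint")
})
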