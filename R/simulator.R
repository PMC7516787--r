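# Simulation engine: synthetic Hardy-Weinberg genotype panels and three
# heritability-calibrated phenotype scenarios (additive; additive +
# polygenic; additive + pairwise epistasis).

#' Simulate a synthetic genotype panel
#'
#' Draws per-SNP allele frequencies from `mafSpec`, samples two haplotypes
#' per individual under Hardy-Weinberg equilibrium, and codes genotypes as
#' \{1, 0, -1\} (the +1 homozygote carries two copies of the frequency-`f`
#' allele). Optional linkage disequilibrium is emulated with a latent
#' first-order autoregressive Gaussian process within blocks of adjacent
#' SNPs, thresholded at the allele-frequency quantile, so marginal
#' frequencies are preserved. SNPs are assigned to `nChrom` chromosomes with
#' increasing base-pair positions.
#'
#' @param n individuals.
#' @param p SNPs.
#' @param mafSpec either a length-2 range for uniform allele-frequency draws
#'   (default `c(0.05, 0.5)`) or a length-p vector of frequencies.
#' @param nChrom chromosome count (default 5).
#' @param ldRho latent AR(1) correlation between adjacent SNPs (0 = none).
#' @param ldBlockSize block length within which the AR(1) correlation runs.
#' @param seed optional integer seed.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(n, p, mafSpec = c(0.05, 0.5), nChrom = 5,
                              ldRho = 0, ldBlockSize = 100, seed = NULL) {
  if (n < 1 || p < 1) stop("n and p must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (length(mafSpec) == 2 && p != 2) {
    if (any(mafSpec <= 0) || any(mafSpec >= 1) || mafSpec[1] > mafSpec[2])
      stop("invalid allele-frequency range")
    f <- runif(p, mafSpec[1], mafSpec[2])
  } else {
    if (length(mafSpec) != p) stop("mafSpec must be a range or length-p vector")
    if (any(mafSpec <= 0) || any(mafSpec >= 1))
      stop("allele frequencies must lie in (0, 1)")
    f <- as.numeric(mafSpec)
  }
  X <- .sampleHweGenotypes(n, p, f, ldRho, ldBlockSize)
  map <- .syntheticMap(p, nChrom)
  validateGenotypes(X, map)
}

.sampleHweGenotypes <- function(n, p, f, ldRho = 0, ldBlockSize = 100) {
  hap <- function() {
    if (ldRho == 0) {
      Z <- matrix(rnorm(n * p), n, p)
    } else {
      Z <- matrix(rnorm(n * p), n, p)
      w <- sqrt(1 - ldRho^2)
      for (j in seq(2, p)) {
        if ((j - 1) %% ldBlockSize == 0) next  # block boundary
        Z[, j] <- ldRho * Z[, j - 1] + w * Z[, j]
      }
    }
    # allele indicator: 1 with probability f[j]
    Z < matrix(qnorm(f), n, p, byrow = TRUE)
  }
  (hap() + hap()) - 1
}

.syntheticMap <- function(p, nChrom) {
  chrom <- rep(seq_len(nChrom), each = ceiling(p / nChrom))[seq_len(p)]
  pos <- unlist(lapply(split(seq_len(p), chrom), function(idx)
    cumsum(sample(200:800, length(idx), replace = TRUE))), use.names = FALSE)
  data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
             chrom = as.integer(chrom), pos = as.numeric(pos),
             stringsAsFactors = FALSE)
}

#' Phenotypic variance budget of a simulation scenario
#'
#' Solves the variance-accounting identity
#' \deqn{V_P = \left(\sum_i h_i\right) V_P + \sigma^2_{pg} +
#'   \sigma^2_{epi,total} + \sigma^2_e}
#' for the total phenotypic variance and reports the implied polygenic and
#' per-pair epistatic heritabilities.
#'
#' @param heritabilities per-QTN heritabilities (sum < 1).
#' @param sigma2e residual variance.
#' @param sigma2pg polygenic variance (0 when absent).
#' @param sigma2epiPerPair vector of per-pair epistatic variances (empty when
#'   absent).
#' @return list with `VP`, `h2pg`, `h2epiPerPair`, `sigma2epiTotal`.
#' @export
varianceBudget <- function(heritabilities, sigma2e, sigma2pg = 0,
                           sigma2epiPerPair = numeric(0)) {
  hsum <- sum(heritabilities)
  if (hsum >= 1) stop("heritabilities must sum to less than 1")
  s2epi <- sum(sigma2epiPerPair)
  VP <- (sigma2e + sigma2pg + s2epi) / (1 - hsum)
  list(VP = VP, h2pg = sigma2pg / VP,
       h2epiPerPair = if (length(sigma2epiPerPair))
         sigma2epiPerPair / VP else numeric(0),
       sigma2epiTotal = s2epi)
}

#' Additive effects that realize the target heritabilities
#'
#' Given per-QTN heritabilities and allele frequencies, computes the effect
#' sizes \eqn{b_i = \sqrt{h_i V_P / \mathrm{Var}(x_i)}} (positive sign
#' convention) with \eqn{\mathrm{Var}(x_i) = 2 f_i (1 - f_i)} under
#' Hardy-Weinberg for the \{1, 0, -1\} coding, where \eqn{V_P} comes from
#' [varianceBudget()].
#'
#' @inheritParams varianceBudget
#' @param mafs per-QTN allele frequencies.
#' @param sigma2epiTotal total epistatic variance across pairs.
#' @return numeric effect vector `b`, with the budget attached as attribute
#'   `"budget"`.
#' @export
effectsFromHeritability <- function(heritabilities, mafs, sigma2e,
                                    sigma2pg = 0, sigma2epiTotal = 0) {
  if (length(mafs) != length(heritabilities))
    stop("mafs and heritabilities must have equal length")
  budget <- varianceBudget(heritabilities, sigma2e, sigma2pg,
                           sigma2epiPerPair = sigma2epiTotal)
  vx <- 2 * mafs * (1 - mafs)
  b <- sqrt(heritabilities * budget$VP / vx)
  attr(b, "budget") <- budget
  b
}

#' Construct a SimTruth object
#'
#' @param qtnIndices,qtnEffects,heritabilities per-QTN truth.
#' @param mu overall mean.
#' @param sigma2e residual variance.
#' @param sigma2pg polygenic variance (0 = absent).
#' @param epistaticPairs matrix with columns `a`, `b`, `effect` (or `NULL`).
#' @param kinship n x n kinship matrix (or `NULL`).
#' @param qtnChrom,qtnPos QTN coordinates (filled from a panel map by
#'   [simulateScenario()]).
#' @return a [SimTruth-class].
#' @export
simTruth <- function(qtnIndices, qtnEffects, heritabilities, mu = 10,
                     sigma2e = 10, sigma2pg = 0, epistaticPairs = NULL,
                     kinship = NULL, qtnChrom = NULL, qtnPos = NULL) {
  m <- length(qtnIndices)
  if (is.null(epistaticPairs))
    epistaticPairs <- matrix(numeric(0), 0, 3,
                             dimnames = list(NULL, c("a", "b", "effect")))
  if (is.null(kinship)) kinship <- matrix(numeric(0), 0, 0)
  if (is.null(qtnChrom)) qtnChrom <- rep(NA_integer_, m)
  if (is.null(qtnPos)) qtnPos <- rep(NA_real_, m)
  new("SimTruth", qtnIndices = as.integer(qtnIndices),
      qtnEffects = as.numeric(qtnEffects),
      qtnChrom = as.integer(qtnChrom), qtnPos = as.numeric(qtnPos),
      heritabilities = as.numeric(heritabilities), mu = mu,
      sigma2e = sigma2e, sigma2pg = sigma2pg,
      epistaticPairs = epistaticPairs, kinship = kinship)
}

#' Marker-based kinship matrix
#'
#' VanRaden-style standardized cross-product: columns are centered and
#' scaled to unit variance (zero-variance SNPs are skipped with a warning)
#' and \eqn{K = Z Z^T / p}. The result is symmetric and positive
#' semi-definite up to numerical tolerance.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @return n x n kinship matrix.
#' @export
kinshipMatrix <- function(G) {
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("%d zero-variance SNP(s) skipped in the kinship computation",
                    sum(!keep)))
  Z <- scale(X[, keep, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  (K + t(K)) / 2
}

#' Simulate a phenotype under one of three genetic architectures
#'
#' Scenario 1: \eqn{y = \mu + \sum_i x_i b_i + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma^2_e I)}. Scenario 2 adds a polygenic
#' vector \eqn{u \sim MVN(0, \sigma^2_{pg} K)}. Scenario 3 adds pairwise
#' epistatic terms \eqn{b_{jj} (x_{A_j} \odot x_{B_j})} (Hadamard products)
#' at loci distinct from the additive QTNs.
#'
#' @param G a [GenotypeMatrix-class] consistent with `truth`.
#' @param truth a [SimTruth-class].
#' @param scenario 1, 2 or 3.
#' @param seed optional integer seed.
#' @return a [PhenotypeVector-class] (stage `"raw"`).
#' @export
simulatePhenotype <- function(G, truth, scenario = 1, seed = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), is(truth, "SimTruth"),
            scenario %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  X <- genotypes(G)
  n <- nrow(X)
  if (max(truth@qtnIndices) > ncol(X))
    stop("truth refers to SNP columns beyond the panel")
  g <- truth@mu +
    drop(X[, truth@qtnIndices, drop = FALSE] %*% truth@qtnEffects)
  if (scenario == 2) {
    K <- truth@kinship
    if (!nrow(K)) K <- kinshipMatrix(G)
    if (nrow(K) != n) stop("kinship dimension does not match the panel")
    ev <- eigen(K, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    u <- ev$vectors %*% (sqrt(truth@sigma2pg * lam) * rnorm(n))
    g <- g + drop(u)
  }
  if (scenario == 3) {
    ep <- truth@epistaticPairs
    if (!nrow(ep)) stop("scenario 3 requires epistatic pairs in the truth")
    if (length(intersect(c(ep[, 1], ep[, 2]), truth@qtnIndices)))
      stop("epistatic loci collide with additive QTN indices")
    for (r in seq_len(nrow(ep)))
      g <- g + ep[r, 3] * (X[, ep[r, 1]] * X[, ep[r, 2]])
  }
  phenotypeVector(g + rnorm(n, 0, sqrt(truth@sigma2e)))
}

#' Simulate a complete study: panel, truth and phenotype
#'
#' The default parameters are the reference simulation conditions of the
#' package: n = 199 individuals, 10,000 SNPs over five chromosomes, six QTNs
#' at allele frequency 0.30 with heritabilities (0.10, 0.05, 0.05, 0.15,
#' 0.05, 0.05), overall mean 10 and residual variance 10; scenario 2 adds a
#' polygenic term with variance 2 (implied polygenic heritability 0.092);
#' scenario 3 adds three epistatic pairs, each contributing variance 1.25
#' (per-pair heritability 0.05). QTN columns are regenerated at the QTN
#' allele frequency and placed at fixed panel quantiles; epistatic pair loci
#' are drawn among the non-QTN SNPs. Effect sizes come from
#' [effectsFromHeritability()] so each QTN realizes its target heritability
#' in expectation; epistatic effects are scaled the same way from the
#' Hardy-Weinberg variance of the product column.
#'
#' @param scenario 1 (additive), 2 (+ polygenic), 3 (+ epistasis).
#' @param n,p panel size.
#' @param heritabilities per-QTN heritabilities.
#' @param qtnMaf allele frequency forced at the QTN columns.
#' @param mu,sigma2e overall mean and residual variance.
#' @param sigma2pg polygenic variance (scenario 2).
#' @param sigma2epiPerPair per-pair epistatic variance (scenario 3);
#'   recycled to `nEpistaticPairs`.
#' @param nEpistaticPairs number of epistatic pairs (scenario 3).
#' @param mafSpec,nChrom,ldRho,ldBlockSize passed to [simulateGenotypes()].
#' @param seed integer seed for the whole draw.
#' @return list with `genotypes` ([GenotypeMatrix-class]), `phenotype`
#'   ([PhenotypeVector-class]) and `truth` ([SimTruth-class]).
#' @export
simulateScenario <- function(scenario = 1, n = 199, p = 10000,
                             heritabilities = c(0.10, 0.05, 0.05, 0.15,
                                                0.05, 0.05),
                             qtnMaf = 0.30, mu = 10, sigma2e = 10,
                             sigma2pg = 2, sigma2epiPerPair = 1.25,
                             nEpistaticPairs = 3,
                             mafSpec = c(0.05, 0.5), nChrom = 5,
                             ldRho = 0, ldBlockSize = 100, seed = NULL) {
  stopifnot(scenario %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  nQtn <- length(heritabilities)
  if (p < nQtn + 2 * nEpistaticPairs)
    stop("panel too small for the requested QTN/epistasis layout")
  G <- simulateGenotypes(n, p, mafSpec, nChrom, ldRho, ldBlockSize,
                         seed = NULL)
  # QTNs at fixed panel quantiles, regenerated at the QTN allele frequency
  qtnIdx <- unique(pmax(1L, pmin(p, round(p * (seq_len(nQtn) - 0.5) / nQtn))))
  X <- genotypes(G)
  X[, qtnIdx] <- .sampleHweGenotypes(n, length(qtnIdx),
                                     rep(qtnMaf, length(qtnIdx)))
  G <- validateGenotypes(X, snpMap(G))

  s2pg <- if (scenario == 2) sigma2pg else 0
  epiVar <- if (scenario == 3)
    rep_len(sigma2epiPerPair, nEpistaticPairs) else numeric(0)
  b <- effectsFromHeritability(heritabilities, rep(qtnMaf, nQtn), sigma2e,
                               sigma2pg = s2pg,
                               sigma2epiTotal = sum(epiVar))

  pairs <- NULL
  if (scenario == 3) {
    loci <- sample(setdiff(seq_len(p), qtnIdx), 2 * nEpistaticPairs)
    f <- alleleFrequencies(G)[loci]
    ex2 <- 1 - 2 * f * (1 - f)          # E[x^2] under HWE
    m1 <- 2 * f - 1                     # E[x]
    a <- loci[seq_len(nEpistaticPairs)]
    bb <- loci[nEpistaticPairs + seq_len(nEpistaticPairs)]
    ia <- seq_len(nEpistaticPairs); ib <- nEpistaticPairs + ia
    varProd <- ex2[ia] * ex2[ib] - (m1[ia] * m1[ib])^2
    bjj <- sqrt(epiVar / varProd)
    pairs <- cbind(a = a, b = bb, effect = bjj)
  }

  K <- if (scenario == 2) kinshipMatrix(G) else NULL
  map <- snpMap(G)
  truth <- simTruth(qtnIdx, as.numeric(b), heritabilities, mu = mu,
                    sigma2e = sigma2e, sigma2pg = s2pg,
                    epistaticPairs = pairs, kinship = K,
                    qtnChrom = map$chrom[qtnIdx], qtnPos = map$pos[qtnIdx])
  y <- simulatePhenotype(G, truth, scenario, seed = NULL)
  list(genotypes = G, phenotype = y, truth = truth)
}

#' Write / read simulation ground truth as JSON
#'
#' The kinship matrix is not serialized (it is recomputable from the panel);
#' everything else round-trips.
#'
#' @param truth a [SimTruth-class].
#' @param file path.
#' @return `writeSimTruth`: invisibly, the path. `readSimTruth`: a
#'   [SimTruth-class].
#' @export
writeSimTruth <- function(truth, file) {
  stopifnot(is(truth, "SimTruth"))
  obj <- list(qtn_indices = truth@qtnIndices,
              qtn_effects = truth@qtnEffects,
              qtn_chrom = truth@qtnChrom, qtn_pos = truth@qtnPos,
              heritabilities = truth@heritabilities,
              mu = truth@mu, sigma2_e = truth@sigma2e,
              sigma2_pg = truth@sigma2pg,
              epistatic_pairs = if (nrow(truth@epistaticPairs))
                unname(apply(truth@epistaticPairs, 1, as.list)) else list())
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  pairs <- NULL
  ep <- obj$epistatic_pairs
  if (length(ep)) {
    pm <- if (is.data.frame(ep)) as.matrix(ep[, c("a", "b", "effect")])
          else do.call(rbind, lapply(ep, function(r)
            unlist(r)[c("a", "b", "effect")]))
    pairs <- matrix(as.numeric(pm), ncol = 3,
                    dimnames = list(NULL, c("a", "b", "effect")))
  }
  simTruth(obj$qtn_indices, obj$qtn_effects, obj$heritabilities,
           mu = obj$mu, sigma2e = obj$sigma2_e, sigma2pg = obj$sigma2_pg,
           epistaticPairs = pairs,
           qtnChrom = obj$qtn_chrom, qtnPos = obj$qtn_pos)
}

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d QTNs (sum h2 = %.2f), mu = %g, sigma2e = %g",
              length(object@qtnIndices), sum(object@heritabilities),
              object@mu, object@sigma2e))
  if (object@sigma2pg > 0) cat(sprintf(", sigma2pg = %g", object@sigma2pg))
  if (nrow(object@epistaticPairs))
    cat(sprintf(", %d epistatic pair(s)", nrow(object@epistaticPairs)))
  cat("\n")
  invisible(object)
})
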