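#' @import methods
#' @importFrom stats var sd cor pchisq rnorm runif qnorm coef
#' @importFrom utils read.table write.table head
#' @useDynLib mblasso, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.GENO_CODES <- c(-1L, 0L, 1L)

#' GenotypeMatrix: an additively coded SNP panel
#'
#' Stores an \eqn{n \times p} genotype matrix with entries in \{1, 0, -1\}
#' (the two homozygotes coded 1 and -1, the heterozygote 0) together with a
#' SNP map giving, per column, the SNP identifier, chromosome and base-pair
#' position. Construct with [validateGenotypes()] which checks the coding and
#' the map; direct `new()` calls are validated the same way.
#'
#' @slot X numeric matrix of genotype codes, individuals in rows.
#' @slot snpMap `data.frame` with columns `snp_id`, `chrom`, `pos`;
#'   one row per SNP column, `(chrom, pos)` unique, `pos` non-negative.
#'
#' @seealso [validateGenotypes()], [mafFilter()], [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix",
  slots = c(X = "matrix", snpMap = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  X <- object@X
  map <- object@snpMap
  if (!is.numeric(X)) return("genotype matrix must be numeric")
  if (anyNA(X)) return("genotype matrix contains missing values; impute or drop before construction")
  bad <- which(!(X %in% .GENO_CODES))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(X)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(X)) + 1L
    return(sprintf("invalid genotype code %s at row %d, column %d (allowed: 1, 0, -1)",
                   format(X[bad[1]]), i, j))
  }
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    return("snpMap must have columns snp_id, chrom, pos")
  if (nrow(map) != ncol(X))
    return(sprintf("snpMap has %d rows but genotype matrix has %d SNP columns",
                   nrow(map), ncol(X)))
  if (any(map$pos < 0) || any(map$pos != round(map$pos)))
    return("positions must be non-negative integers")
  if (anyDuplicated(map[, c("chrom", "pos")]))
    return("(chrom, pos) pairs must be unique")
  TRUE
})

#' PhenotypeVector: a quantitative trait with its correction stage
#'
#' A numeric vector of trait values that records which correction stage it
#' represents: `"raw"` (y), `"corrected"` (y' after fixed-effect removal) or
#' `"screen-corrected"` (y'' after subtracting screened SNP contributions).
#' Behaves as an ordinary numeric vector in arithmetic.
#'
#' @slot stage character, one of `"raw"`, `"corrected"`, `"screen-corrected"`.
#' @export
setClass("PhenotypeVector", contains = "numeric",
  slots = c(stage = "character"),
  prototype = prototype(stage = "raw"))

setValidity("PhenotypeVector", function(object) {
  if (length(object@stage) != 1L ||
      !object@stage %in% c("raw", "corrected", "screen-corrected"))
    return("stage must be one of 'raw', 'corrected', 'screen-corrected'")
  if (any(!is.finite(object@.Data)))
    return("phenotype values must all be finite")
  TRUE
})

#' FixedEffects: covariate matrix for phenotype correction
#'
#' An \eqn{n \times q} matrix of fixed-effect covariates (for instance
#' population-structure proportions) and, once [correctPhenotype()] has run,
#' the least-squares coefficient estimates.
#'
#' @slot Q numeric matrix, `n` rows by `q` columns; `q = 0` means no
#'   correction.
#' @slot alphaHat numeric, length 0 (not yet estimated) or `q`.
#' @export
setClass("FixedEffects",
  slots = c(Q = "matrix", alphaHat = "numeric"),
  prototype = prototype(Q = matrix(numeric(0), 0, 0), alphaHat = numeric(0)))

setValidity("FixedEffects", function(object) {
  if (!is.numeric(object@Q)) return("Q must be numeric")
  if (length(object@alphaHat) &&
      length(object@alphaHat) != ncol(object@Q))
    return("alphaHat length must equal ncol(Q)")
  TRUE
})

#' ScreenResult: one measure's screening outcome
#'
#' Records, for one association measure (Pearson correlation or mutual
#' information), the length-p marginal score vector, the Type I SNP set
#' (nonzero SCAD effects after the first screen) and the Type II set (revived
#' by one ISIS iteration on the complement). The two sets are disjoint by
#' construction; their union is the measure's candidate set.
#'
#' @slot scores numeric length-p marginal scores (Pearson r, or MI in nats).
#' @slot typeI integer indices of Type I SNPs (1-based columns).
#' @slot typeII integer indices of Type II SNPs.
#' @slot measure `"pearson"` or `"mutual_information"`.
#' @export
setClass("ScreenResult",
  slots = c(scores = "numeric", typeI = "integer", typeII = "integer",
            measure = "character"))

setValidity("ScreenResult", function(object) {
  if (!object@measure %in% c("pearson", "mutual_information"))
    return("measure must be 'pearson' or 'mutual_information'")
  if (length(intersect(object@typeI, object@typeII)))
    return("typeI and typeII sets must be disjoint")
  p <- length(object@scores)
  if (length(object@typeI) && (min(object@typeI) < 1 || max(object@typeI) > p))
    return("typeI indices out of range")
  if (length(object@typeII) && (min(object@typeII) < 1 || max(object@typeII) > p))
    return("typeII indices out of range")
  TRUE
})

#' ScadFit: a SCAD-penalized least-squares fit
#'
#' @slot beta coefficient vector on the original predictor scale.
#' @slot betaStd coefficients on the internally standardized scale (these are
#'   what the penalty was applied to).
#' @slot intercept unpenalized intercept.
#' @slot lambda selected penalty level.
#' @slot gamma SCAD shrinkage parameter (> 2).
#' @slot nonzero integer indices with exactly nonzero coefficients.
#' @slot objective penalized objective at the solution:
#'   \eqn{RSS/(2n) + \sum_j \rho_{\lambda,\gamma}(|\beta_j^{std}|)}.
#' @slot lambdaPath the full decreasing penalty path that was searched.
#' @slot criterion the per-path selection criterion values (BIC or CV error).
#' @slot nIter coordinate-descent sweep count at the selected penalty.
#' @slot converged logical.
#' @export
setClass("ScadFit",
  slots = c(beta = "numeric", betaStd = "numeric", intercept = "numeric",
            lambda = "numeric", gamma = "numeric", nonzero = "integer",
            objective = "numeric", lambdaPath = "numeric",
            criterion = "numeric", nIter = "integer", converged = "logical"))

setValidity("ScadFit", function(object) {
  if (object@gamma <= 2) return("gamma must be > 2")
  if (object@lambda < 0) return("lambda must be non-negative")
  if (!setequal(object@nonzero, which(object@beta != 0)))
    return("nonzero set inconsistent with beta")
  TRUE
})

#' EmBlassoFit: an EM Bayesian Lasso fit
#'
#' Hierarchical shrinkage fit of `y = 1 mu + X beta + e` with per-effect
#' normal priors `beta_j ~ N(0, sigma2_j)`; the EM algorithm drives variance
#' components of unsupported effects to zero. Effects with `|beta| <` the
#' drop tolerance (default 1e-5) are zeroed after convergence.
#'
#' @slot mu estimated overall mean.
#' @slot beta effect estimates (zeros for dropped effects).
#' @slot sigma2e residual-variance estimate (> 0).
#' @slot sigma2j per-effect prior variance components at convergence.
#' @slot retained indices with `|beta| >=` drop tolerance.
#' @slot dropTol the drop tolerance used.
#' @slot nIter iterations run.
#' @slot converged logical.
#' @slot logPosterior per-iteration observed-data log-posterior trace
#'   (marginal Gaussian likelihood plus variance-component prior).
#' @export
setClass("EmBlassoFit",
  slots = c(mu = "numeric", beta = "numeric", sigma2e = "numeric",
            sigma2j = "numeric", retained = "integer", dropTol = "numeric",
            nIter = "integer", converged = "logical",
            logPosterior = "numeric"))

setValidity("EmBlassoFit", function(object) {
  if (object@sigma2e <= 0) return("sigma2e must be positive")
  b <- object@beta
  r <- object@retained
  if (length(r) && any(abs(b[r]) < object@dropTol))
    return("retained set contains effects below the drop tolerance")
  if (length(b) && length(setdiff(which(abs(b) >= object@dropTol), r)))
    return("effects at or above the drop tolerance must be in the retained set")
  TRUE
})

#' SimTruth: ground truth of a simulated trait
#'
#' @slot qtnIndices column indices of the true QTNs in the genotype panel.
#' @slot qtnEffects true additive effects `b_i`.
#' @slot qtnChrom,qtnPos chromosome and base-pair position of each QTN.
#' @slot heritabilities per-QTN heritabilities, each in (0,1), sum < 1.
#' @slot mu overall mean.
#' @slot sigma2e residual variance.
#' @slot sigma2pg polygenic variance (0 when absent).
#' @slot epistaticPairs numeric matrix with columns `a`, `b`, `effect`
#'   (0 rows when absent); loci distinct from the additive QTNs.
#' @slot kinship n x n kinship matrix (0 x 0 when absent).
#' @export
setClass("SimTruth",
  slots = c(qtnIndices = "integer", qtnEffects = "numeric",
            qtnChrom = "integer", qtnPos = "numeric",
            heritabilities = "numeric", mu = "numeric", sigma2e = "numeric",
            sigma2pg = "numeric", epistaticPairs = "matrix",
            kinship = "matrix"))

setValidity("SimTruth", function(object) {
  h <- object@heritabilities
  if (any(h <= 0) || any(h >= 1)) return("heritabilities must lie in (0,1)")
  if (sum(h) >= 1) return("heritabilities must sum to less than 1")
  m <- length(object@qtnIndices)
  if (length(object@qtnEffects) != m || length(h) != m)
    return("qtnIndices, qtnEffects and heritabilities must have equal length")
  if (object@sigma2e <= 0) return("sigma2e must be positive")
  if (object@sigma2pg < 0) return("sigma2pg must be non-negative")
  ep <- object@epistaticPairs
  if (nrow(ep) && ncol(ep) != 3)
    return("epistaticPairs must have columns a, b, effect")
  if (nrow(ep) && length(intersect(c(ep[, 1], ep[, 2]), object@qtnIndices)))
    return("epistatic loci must be distinct from the additive QTNs")
  K <- object@kinship
  if (nrow(K)) {
    if (nrow(K) != ncol(K)) return("kinship must be square")
    if (max(abs(K - t(K))) > 1e-8) return("kinship must be symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev)))
      return("kinship must be positive semi-definite")
  }
  TRUE
})

#' AssociationResult: the final association table
#'
#' One row per tested SNP with its stage-2 effect estimate, LOD score,
#' likelihood-ratio p-value and significance flag (`lod >= threshold`).
#' Stage bookkeeping (screened set sizes k1..k3, tau1..tau3, nu, overlap)
#' is kept in `stageSizes`.
#'
#' @slot table `data.frame` with columns `snp_id`, `chrom`, `pos`, `effect`,
#'   `lod`, `p_value`, `significant`.
#' @slot threshold LOD significance threshold (default 3).
#' @slot stageSizes named list of per-stage counts.
#' @export
setClass("AssociationResult",
  slots = c(table = "data.frame", threshold = "numeric",
            stageSizes = "list"),
  prototype = prototype(threshold = 3, stageSizes = list()))

setValidity("AssociationResult", function(object) {
  need <- c("snp_id", "chrom", "pos", "effect", "lod", "p_value", "significant")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  tab <- object@table
  if (nrow(tab) && !identical(as.logical(tab$significant),
                              as.logical(tab$lod >= object@threshold)))
    return("significant flag must equal lod >= threshold")
  TRUE
})

#' JointDistribution: empirical joint table of a SNP and a binned phenotype
#'
#' @slot counts non-negative count matrix (genotype states x phenotype bins).
#' @slot nObs total count.
#' @export
setClass("JointDistribution",
  slots = c(counts = "matrix", nObs = "numeric"))

setValidity("JointDistribution", function(object) {
  cts <- object@counts
  if (any(cts < 0)) return("counts must be non-negative")
  if (sum(cts) <= 0) return("counts must not be all zero")
  if (abs(sum(cts) - object@nObs) > 1e-8)
    return("nObs must equal the total count")
  TRUE
})
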