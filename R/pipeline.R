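#' Pipeline configuration
#'
#' Collects every tunable of the two-stage pipeline with its default.
#' Flags given to the command-line interface override these values.
#'
#' @param measure which screening measure(s) to run: `"both"` (the full
#'   two-measure method), `"pearson"` (the Pearson-only ISIS pathway) or
#'   `"mi"`.
#' @param lodThreshold significance cutoff on the LOD score (default 3).
#' @param bins phenotype bin count for mutual information; `NULL` means
#'   `round(sqrt(n))`.
#' @param smoothing Laplace pseudo-count per joint-table cell (default 0).
#' @param gamma SCAD shrinkage parameter (default 3.7).
#' @param lambdaStrategy SCAD penalty selection: `"bic"` (deterministic
#'   default) or `"cv"`.
#' @param nlambda,lambdaMinRatio SCAD penalty path (100 points down to
#'   0.001 of the path maximum).
#' @param cvFolds folds when `lambdaStrategy = "cv"`.
#' @param scadTol,scadMaxIter coordinate-descent convergence controls.
#' @param screenSize `"n-1"` (default) or `"n/logn"` screened-set size.
#' @param emMaxIter,emTol EM Bayesian Lasso controls.
#' @param priorDf,priorScale variance-component hyperprior (tau, omega).
#' @param dropTol stage-2 effect drop rule (default 1e-5).
#' @param singleStageCap largest panel [runEmblassoSingleStage()] accepts.
#' @param seed optional integer seed recorded in the config (used by
#'   stochastic components; the default pipeline is deterministic).
#' @param verbose log per-stage set sizes to stderr.
#' @return a named list of class `mblassoConfig`.
#' @export
mblassoConfig <- function(measure = c("both", "pearson", "mi"),
                          lodThreshold = 3, bins = NULL, smoothing = 0,
                          gamma = 3.7,
                          lambdaStrategy = c("bic", "cv"),
                          nlambda = 100, lambdaMinRatio = 0.001,
                          cvFolds = 10, scadTol = 1e-7, scadMaxIter = 10000,
                          screenSize = c("n-1", "n/logn"),
                          emMaxIter = 1000, emTol = 1e-8,
                          priorDf = -1, priorScale = 0, dropTol = 1e-5,
                          singleStageCap = 5000, seed = NULL,
                          verbose = FALSE) {
  cfg <- list(measure = match.arg(measure), lodThreshold = lodThreshold,
              bins = bins, smoothing = smoothing, gamma = gamma,
              lambdaStrategy = match.arg(lambdaStrategy),
              nlambda = nlambda, lambdaMinRatio = lambdaMinRatio,
              cvFolds = cvFolds, scadTol = scadTol,
              scadMaxIter = scadMaxIter,
              screenSize = match.arg(screenSize),
              emMaxIter = emMaxIter, emTol = emTol,
              priorDf = priorDf, priorScale = priorScale,
              dropTol = dropTol, singleStageCap = singleStageCap,
              seed = seed, verbose = verbose)
  class(cfg) <- "mblassoConfig"
  cfg
}

.log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

.emptyAssociation <- function(threshold, stageSizes = list()) {
  new("AssociationResult",
      table = data.frame(snp_id = character(0), chrom = integer(0),
                         pos = numeric(0), effect = numeric(0),
                         lod = numeric(0), p_value = numeric(0),
                         significant = logical(0),
                         stringsAsFactors = FALSE),
      threshold = threshold, stageSizes = stageSizes)
}

# Stage 2 + LRT on a candidate index set; shared by both pipeline modes.
.stage2 <- function(G, yRaw, candidates, config, stageSizes) {
  X <- genotypes(G)
  map <- snpMap(G)
  em <- emBlassoFit(yRaw, X[, candidates, drop = FALSE],
                    maxIter = config$emMaxIter, tol = config$emTol,
                    priorDf = config$priorDf,
                    priorScale = config$priorScale,
                    dropTol = config$dropTol)
  keep <- retainedSet(em)
  stageSizes$retained <- length(keep)
  .log_stage(config, "stage 2: %d of %d candidates retained (|beta| >= %g)",
             length(keep), length(candidates), config$dropTol)
  if (!length(keep)) {
    warning("no effect survived the stage-2 shrinkage; empty result")
    return(.emptyAssociation(config$lodThreshold, stageSizes))
  }
  global <- candidates[keep]
  XR <- X[, global, drop = FALSE]
  tests <- lapply(seq_along(global), function(k) testMarker(yRaw, XR, k))
  tab <- data.frame(snp_id = map$snp_id[global],
                    chrom = map$chrom[global],
                    pos = map$pos[global],
                    effect = em@beta[keep],
                    lod = vapply(tests, `[[`, numeric(1), "lod"),
                    p_value = vapply(tests, `[[`, numeric(1), "pValue"),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$lod >= config$lodThreshold
  new("AssociationResult", table = tab, threshold = config$lodThreshold,
      stageSizes = stageSizes)
}

#' Run the full two-stage multi-locus association pipeline
#'
#' Executes, in order: fixed-effect phenotype correction; Pearson SIS-SCAD
#' plus one ISIS iteration; the mutual-information analogue; the
#' de-duplicated union of the two candidate sets; EM Bayesian Lasso effect
#' estimation on the ORIGINAL phenotype; a nested likelihood-ratio test per
#' retained marker; and the LOD-threshold significance call. Identical
#' inputs and configuration give identical results (the default pipeline
#' has no stochastic step).
#'
#' @param G a [GenotypeMatrix-class].
#' @param y the raw phenotype (numeric or [PhenotypeVector-class]).
#' @param Q optional fixed effects ([FixedEffects-class] or matrix).
#' @param config a [mblassoConfig()] list.
#' @return an [AssociationResult-class]; `stageSizes` records k1..k3,
#'   tau1..tau3, nu and the screening overlap.
#' @export
runMblasso <- function(G, y, Q = NULL, config = mblassoConfig()) {
  stopifnot(is(G, "GenotypeMatrix"))
  yRaw <- as.numeric(y)
  if (length(yRaw) != nIndividuals(G))
    stop("phenotype length must equal the number of individuals")
  X <- genotypes(G)
  yPrime <- correctPhenotype(yRaw, Q)

  stageSizes <- list()
  A <- B <- NULL
  if (config$measure %in% c("both", "pearson")) {
    A <- screenPanel(X, yPrime, "pearson", config)
    stageSizes$k1 <- length(suppressWarnings(
      topSelect(screenScores(A), .screenSize(nrow(X), config$screenSize), TRUE)))
    stageSizes$k2 <- length(typeISet(A))
    stageSizes$k3 <- length(typeIISet(A))
    .log_stage(config, "pearson screen: k1=%d k2=%d k3=%d",
               stageSizes$k1, stageSizes$k2, stageSizes$k3)
  }
  if (config$measure %in% c("both", "mi")) {
    B <- screenPanel(X, yPrime, "mi", config)
    stageSizes$tau1 <- length(suppressWarnings(
      topSelect(screenScores(B), .screenSize(nrow(X), config$screenSize), FALSE)))
    stageSizes$tau2 <- length(typeISet(B))
    stageSizes$tau3 <- length(typeIISet(B))
    .log_stage(config, "MI screen: tau1=%d tau2=%d tau3=%d",
               stageSizes$tau1, stageSizes$tau2, stageSizes$tau3)
  }
  if (!is.null(A) && !is.null(B)) {
    u <- unionCandidates(A, B)
    candidates <- u$candidates
    stageSizes$overlap <- u$overlap
  } else {
    candidates <- unionSet(if (!is.null(A)) A else B)
  }
  stageSizes$nu <- length(candidates)
  .log_stage(config, "candidate union: nu=%d", stageSizes$nu)

  if (!length(candidates)) {
    warning("empty candidate set after screening; returning an empty result")
    return(.emptyAssociation(config$lodThreshold, stageSizes))
  }
  .stage2(G, yRaw, candidates, config, stageSizes)
}

#' Single-stage EM Bayesian Lasso association (no pre-screening)
#'
#' Fits the stage-2 shrinkage model directly on every SNP in the panel and
#' applies the likelihood-ratio test to the retained effects. This is the
#' single-stage comparison method; it is only feasible for moderate panels,
#' so panels larger than `config$singleStageCap` are refused with advice to
#' use the screening pipeline.
#'
#' @inheritParams runMblasso
#' @return an [AssociationResult-class].
#' @export
runEmblassoSingleStage <- function(G, y, Q = NULL, config = mblassoConfig()) {
  stopifnot(is(G, "GenotypeMatrix"))
  p <- nSnps(G)
  if (p > config$singleStageCap)
    stop(sprintf("panel has %d SNPs, above the single-stage cap of %d; use runMblasso (screening) instead",
                 p, config$singleStageCap))
  yRaw <- as.numeric(y)
  if (length(yRaw) != nIndividuals(G))
    stop("phenotype length must equal the number of individuals")
  # Q is accepted for interface symmetry; stage 2 works on the original y
  .stage2(G, yRaw, seq_len(p), config,
          stageSizes = list(nu = p, mode = "single-stage"))
}
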