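# Stage-1 screening: sure-independence screening under Pearson correlation
# or mutual information, refined by SCAD, plus a single ISIS iteration on
# the complement set.

#' Pearson correlation scores for a panel
#'
#' Marginal Pearson correlation of every SNP column with the (corrected)
#' phenotype. Constant SNP columns score 0 with a warning; a constant
#' phenotype is an error.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @param yPrime numeric phenotype.
#' @return numeric vector of correlations, length p.
#' @export
pearsonScores <- function(G, yPrime) {
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  yv <- as.numeric(yPrime)
  if (length(yv) != nrow(X))
    stop("phenotype length must equal the individual count")
  if (stats::sd(yv) == 0) stop("constant phenotype: correlations are undefined")
  w <- suppressWarnings(as.numeric(cor(X, yv)))
  if (anyNA(w)) {
    warning(sprintf("%d constant SNP column(s) scored 0", sum(is.na(w))))
    w[is.na(w)] <- 0
  }
  w
}

#' Select the top-scoring SNPs, including cutoff ties
#'
#' Returns the indices whose score is at least the `k`-th largest value.
#' All ties at the cutoff are included, so more than `k` indices may be
#' returned (several SNPs can share a score). Pearson screening passes
#' absolute scores; MI scores are non-negative and used raw.
#'
#' @param scores numeric score vector.
#' @param k number of SNPs to keep (screening uses `n - 1`).
#' @param useAbsolute rank by `|score|` (Pearson) rather than the raw value
#'   (MI).
#' @return integer index vector (ascending).
#' @export
topSelect <- function(scores, k, useAbsolute = TRUE) {
  if (k < 1) stop("k must be at least 1")
  v <- if (useAbsolute) abs(scores) else as.numeric(scores)
  p <- length(v)
  if (p <= k) {
    warning(sprintf("panel has %d SNPs, not more than the screening size %d; keeping all", p, k))
    return(seq_len(p))
  }
  cutoff <- sort(v, decreasing = TRUE)[k]
  which(v >= cutoff)
}

.screenSize <- function(n, rule = c("n-1", "n/logn")) {
  rule <- match.arg(rule)
  if (rule == "n-1") n - 1L else max(1L, floor(n / log(n)))
}

.marginalScores <- function(X, yv, measure, config) {
  if (measure == "pearson") pearsonScores(X, yv)
  else miScores(X, yv,
                bins = if (is.null(config$bins))
                  max(2L, round(sqrt(length(yv)))) else config$bins,
                smoothing = config$smoothing)
}

.scadOnColumns <- function(yv, X, cols, config) {
  scadFit(yv, X[, cols, drop = FALSE], gamma = config$gamma,
          lambdaStrategy = config$lambdaStrategy,
          nlambda = config$nlambda, lambdaMinRatio = config$lambdaMinRatio,
          ambientDim = ncol(X),   # screening searched the whole panel
          cvFolds = config$cvFolds, tol = config$scadTol,
          maxIter = config$scadMaxIter)
}

#' One pass of (MI-)SIS-SCAD
#'
#' Ranks the SNPs by the marginal measure, keeps the top `n - 1` (ties
#' included), fits SCAD-penalized regression of the phenotype on the kept
#' columns, and returns the SNPs with exactly nonzero SCAD effect -- the
#' measure's Type I set.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @param yPrime numeric (corrected) phenotype.
#' @param measure `"pearson"` or `"mi"`.
#' @param config a [mblassoConfig()] list.
#' @return list with `typeI` (integer indices into the panel), `fit`
#'   (the [ScadFit-class]), `screened` (the pre-SCAD top set) and `scores`.
#' @export
sisScad <- function(G, yPrime, measure = c("pearson", "mi"),
                    config = mblassoConfig()) {
  measure <- match.arg(measure)
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  yv <- as.numeric(yPrime)
  n <- nrow(X)
  scores <- .marginalScores(X, yv, measure, config)
  k <- .screenSize(n, config$screenSize)
  screened <- topSelect(scores, k, useAbsolute = (measure == "pearson"))
  fit <- .scadOnColumns(yv, X, screened, config)
  names(fit@beta) <- as.character(screened)  # panel-level column mapping
  list(typeI = screened[fit@nonzero], fit = fit,
       screened = screened, scores = scores)
}

#' One ISIS iteration on the complement set
#'
#' Subtracts the SCAD-estimated contribution of the Type I SNPs from the
#' corrected phenotype (`y'' = y' - X_I beta_I`) and reruns SIS-SCAD on the
#' remaining `p - |Type I|` SNPs against `y''`. Exactly one iteration is
#' performed; its nonzero set is the measure's Type II set, disjoint from
#' Type I by construction.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @param yPrime the corrected phenotype used for the first pass.
#' @param typeI integer indices selected by [sisScad()].
#' @param fit the [ScadFit-class] from the same [sisScad()] call (its
#'   coefficients, not a refit, define the correction).
#' @param measure `"pearson"` or `"mi"`.
#' @param config a [mblassoConfig()] list.
#' @return integer vector of Type II indices (possibly empty).
#' @export
isisIteration <- function(G, yPrime, typeI, fit,
                          measure = c("pearson", "mi"),
                          config = mblassoConfig()) {
  measure <- match.arg(measure)
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  yv <- as.numeric(yPrime)
  p <- ncol(X)
  typeI <- as.integer(typeI)
  rest <- setdiff(seq_len(p), typeI)
  if (!length(rest)) return(integer(0))
  ysec <- yv
  if (length(typeI)) {
    bI <- if (!is.null(names(fit@beta)))
      fit@beta[as.character(typeI)] else fit@beta[typeI]
    if (anyNA(bI))
      stop("fit does not carry coefficients for the given typeI set; pass the fit returned by sisScad on the same data")
    ysec <- yv - drop(X[, typeI, drop = FALSE] %*% bI)
  }
  second <- sisScad(X[, rest, drop = FALSE], ysec, measure, config)
  rest[second$typeI]
}

#' Full screening for one association measure
#'
#' Runs [sisScad()] then [isisIteration()] and assembles the
#' [ScreenResult-class] (scores from the first pass, Type I, Type II).
#'
#' @inheritParams sisScad
#' @return a [ScreenResult-class].
#' @export
screenPanel <- function(G, yPrime, measure = c("pearson", "mi"),
                        config = mblassoConfig()) {
  measure <- match.arg(measure)
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  first <- sisScad(X, yPrime, measure, config)
  typeI <- as.integer(first$typeI)
  # correction uses the SCAD estimates from the first fit
  yv <- as.numeric(yPrime)
  rest <- setdiff(seq_len(ncol(X)), typeI)
  typeII <- integer(0)
  if (length(rest)) {
    ysec <- yv
    if (length(typeI)) {
      bI <- first$fit@beta[match(typeI, first$screened)]
      ysec <- yv - drop(X[, typeI, drop = FALSE] %*% bI)
    }
    second <- sisScad(X[, rest, drop = FALSE], ysec, measure, config)
    typeII <- rest[second$typeI]
  }
  new("ScreenResult", scores = first$scores, typeI = typeI,
      typeII = as.integer(typeII),
      measure = if (measure == "pearson") "pearson" else "mutual_information")
}

#' Union of the two measures' candidate sets
#'
#' De-duplicated union of the Pearson and MI candidate sets, with the
#' overlap ratio `|A intersect B| / |A union B|` as a screening diagnostic.
#' Because duplicates are removed the union size is at most `k + tau`.
#'
#' @param A,B [ScreenResult-class] objects from the two measures (or plain
#'   integer index sets).
#' @return list with `candidates` (sorted integer indices) and `overlap`.
#' @export
unionCandidates <- function(A, B) {
  a <- if (is(A, "ScreenResult")) unionSet(A) else sort(unique(as.integer(A)))
  b <- if (is(B, "ScreenResult")) unionSet(B) else sort(unique(as.integer(B)))
  u <- sort(union(a, b))
  ov <- if (length(u)) length(intersect(a, b)) / length(u) else NA_real_
  list(candidates = u, overlap = ov)
}

#' @describeIn screenScores method for ScreenResult
#' @export
setMethod("screenScores", "ScreenResult", function(x) x@scores)

#' @describeIn typeISet method for ScreenResult
#' @export
setMethod("typeISet", "ScreenResult", function(x) x@typeI)

#' @describeIn typeIISet method for ScreenResult
#' @export
setMethod("typeIISet", "ScreenResult", function(x) x@typeII)

#' @describeIn unionSet method for ScreenResult
#' @export
setMethod("unionSet", "ScreenResult", function(x) sort(c(x@typeI, x@typeII)))

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult (%s): %d Type I + %d Type II of %d SNPs\n",
              object@measure, length(object@typeI), length(object@typeII),
              length(object@scores)))
  invisible(object)
})
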