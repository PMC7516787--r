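#' Construct a PhenotypeVector
#'
#' @param values finite numeric trait values.
#' @param stage correction stage label; `"raw"` for an uncorrected trait.
#' @return a [PhenotypeVector-class].
#' @export
phenotypeVector <- function(values, stage = "raw") {
  new("PhenotypeVector", as.numeric(values), stage = stage)
}

#' Construct a FixedEffects covariate set
#'
#' @param Q numeric matrix (or vector, treated as one column) of covariates
#'   such as population-structure proportions; `NULL` or a 0-column matrix
#'   means no correction.
#' @return a [FixedEffects-class] with empty `alphaHat`.
#' @export
fixedEffects <- function(Q = NULL) {
  if (is.null(Q)) Q <- matrix(numeric(0), 0, 0)
  if (!is.matrix(Q)) Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  new("FixedEffects", Q = Q, alphaHat = numeric(0))
}

#' Filter SNPs by minor allele frequency
#'
#' Computes per-SNP allele frequency from the \{1, 0, -1\} code counts,
#' `f = (2 #\{+1\} + #\{0\}) / (2n)`, takes the minor frequency
#' `min(f, 1 - f)`, and keeps columns with MAF at or above the threshold.
#'
#' @param G a [GenotypeMatrix-class].
#' @param threshold MAF cutoff in `[0, 0.5]`; SNPs with MAF `>= threshold`
#'   are kept (so `threshold = 0` is the identity).
#' @return the filtered [GenotypeMatrix-class].
#' @export
mafFilter <- function(G, threshold = 0.01) {
  stopifnot(is(G, "GenotypeMatrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must lie in [0, 0.5]")
  f <- alleleFrequencies(G)
  maf <- pmin(f, 1 - f)
  keep <- which(maf >= threshold)
  if (!length(keep))
    stop(sprintf("empty panel: no SNP passes the MAF >= %g filter", threshold))
  G[, keep]
}

#' Correct a phenotype for fixed effects
#'
#' Regresses the trait on `[1, Q]` by ordinary least squares and subtracts
#' the covariate part only, `y' = y - Q alphaHat`, leaving the grand mean in
#' the corrected trait (the stage-2 shrinkage model fits its own mean). With
#' no covariates the trait is returned unchanged apart from its stage label.
#'
#' @param y numeric vector or [PhenotypeVector-class].
#' @param Q a [FixedEffects-class], numeric matrix, or `NULL` for no
#'   correction.
#' @return a [PhenotypeVector-class] with stage `"corrected"`; the fitted
#'   [FixedEffects-class] (with `alphaHat` filled) is attached as attribute
#'   `"fixedEffects"`.
#' @export
correctPhenotype <- function(y, Q = NULL) {
  yv <- as.numeric(y)
  if (is.null(Q)) Q <- fixedEffects()
  if (!is(Q, "FixedEffects")) Q <- fixedEffects(Q)
  Qm <- Q@Q
  if (ncol(Qm) == 0) {
    out <- phenotypeVector(yv, stage = "corrected")
    attr(out, "fixedEffects") <- Q
    return(out)
  }
  if (nrow(Qm) != length(yv))
    stop(sprintf("Q has %d rows but the phenotype has length %d",
                 nrow(Qm), length(yv)))
  D <- cbind(`(Intercept)` = 1, Qm)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- qrD$pivot[(qrD$rank + 1L):ncol(D)]
    nm <- colnames(D)[drop_cols]
    if (is.null(nm)) nm <- paste0("Q", drop_cols - 1L)
    stop("rank-deficient fixed-effect matrix; collinear column(s): ",
         paste(nm, collapse = ", "))
  }
  cf <- qr.coef(qrD, yv)
  alpha <- cf[-1L]
  out <- phenotypeVector(yv - drop(Qm %*% alpha), stage = "corrected")
  Q@alphaHat <- unname(alpha)
  attr(out, "fixedEffects") <- Q
  out
}

#' Natural-log transform a phenotype
#'
#' @param y numeric vector or [PhenotypeVector-class]; all values must be
#'   strictly positive.
#' @return a [PhenotypeVector-class] of elementwise natural logs (stage is
#'   preserved when `y` is a PhenotypeVector, `"raw"` otherwise).
#' @export
logTransform <- function(y) {
  yv <- as.numeric(y)
  if (any(yv <= 0))
    stop("log transform requires strictly positive phenotype values")
  stage <- if (is(y, "PhenotypeVector")) y@stage else "raw"
  phenotypeVector(log(yv), stage = stage)
}

#' Drop individuals with missing phenotype
#'
#' Removes individuals whose trait value is `NA` and subsets the genotype
#' panel (and optional covariates) to the remaining rows.
#'
#' @param y numeric trait vector, possibly with `NA`.
#' @param G a [GenotypeMatrix-class].
#' @param Q optional covariate matrix or [FixedEffects-class].
#' @return list with elements `y` ([PhenotypeVector-class]), `G`, `Q`
#'   (or `NULL`) and `kept` (row indices retained).
#' @export
dropMissingPhenotype <- function(y, G, Q = NULL) {
  yv <- as.numeric(y)
  keep <- which(!is.na(yv))
  if (!length(keep)) stop("all phenotype values are missing")
  Gk <- G[keep, ]
  Qk <- NULL
  if (!is.null(Q)) {
    Qm <- if (is(Q, "FixedEffects")) Q@Q else as.matrix(Q)
    Qk <- fixedEffects(Qm[keep, , drop = FALSE])
  }
  list(y = phenotypeVector(yv[keep]), G = Gk, Q = Qk, kept = keep)
}
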