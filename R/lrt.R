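# Likelihood-ratio testing with LOD scoring on the stage-2 survivors.

.LOD_CONST <- 2 * log(10)  # = 4.60517..., the 4.6052 divisor

#' LOD score from two natural-log likelihoods
#'
#' \deqn{\mathrm{LOD} = \frac{-2 (L_0 - L_1)}{2\ln 10}} where \eqn{L_0} and
#' \eqn{L_1} are the maximized natural-log likelihoods under the null
#' (marker effect zero) and alternative models. H1 nests H0, so a negative
#' difference can only be numerical noise; it is clamped to 0 with a warning.
#'
#' @param L0,L1 natural-log likelihoods.
#' @return the LOD score.
#' @examples
#' lodScore(0, 2.3026)  # one LOD unit
#' @export
lodScore <- function(L0, L1) {
  if (!is.finite(L0) || !is.finite(L1))
    stop("log-likelihoods must be finite")
  if (L1 < L0) {
    warning("L1 < L0 for nested models; clamping LOD at 0")
    return(0)
  }
  2 * (L1 - L0) / .LOD_CONST
}

# Maximized Gaussian log-likelihood of y on [1, X] with sigma^2 profiled out.
# Rank-deficient designs fall back to a ridge-stabilized solve with warning.
.olsLogLik <- function(y, X) {
  n <- length(y)
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("singular design in likelihood-ratio test; using a ridge-stabilized refit")
    A <- crossprod(D)
    eps <- 1e-8 * mean(diag(A))
    cf <- solve(A + diag(eps, ncol(D)), crossprod(D, y))
    res <- y - drop(D %*% cf)
  } else {
    cf <- qr.coef(qrD, y)
    res <- qr.resid(qrD, y)
  }
  s2 <- max(sum(res^2) / n, .Machine$double.xmin)
  list(logLik = -n / 2 * (log(2 * pi * s2) + 1), coef = drop(cf))
}

#' Likelihood-ratio test of one marker in a multi-marker model
#'
#' `L1` is the maximized Gaussian log-likelihood (residual variance profiled
#' out) of the full model with all `o` retained markers plus the mean; `L0`
#' re-maximizes the model with marker `k` removed, so the remaining
#' `o - 1` effects and the mean are refit -- a proper nested test. The
#' p-value is the upper tail of \eqn{\chi^2_1} at
#' \eqn{\mathrm{LOD} \times 2\ln 10}.
#'
#' @param y numeric phenotype.
#' @param X n x o design of retained markers.
#' @param k column index of the marker under test.
#' @return list with `lod`, `pValue`, and `effect` (the marker's coefficient
#'   in the full model).
#' @export
testMarker <- function(y, X, k) {
  if (!is.matrix(X)) X <- as.matrix(X)
  yv <- as.numeric(y)
  o <- ncol(X)
  if (o < 1) stop("the retained design must have at least one marker")
  if (k < 1 || k > o) stop("marker index out of range")
  full <- .olsLogLik(yv, X)
  null <- .olsLogLik(yv, X[, -k, drop = FALSE])
  lod <- lodScore(null$logLik, full$logLik)
  list(lod = lod,
       pValue = pchisq(lod * .LOD_CONST, df = 1, lower.tail = FALSE),
       effect = unname(full$coef[k + 1L]))
}

#' Flag significant associations at a LOD threshold
#'
#' Re-flags the rows of an association table at a (possibly new) LOD
#' threshold: significant means `lod >= threshold`. Lowering the threshold
#' yields a superset of calls.
#'
#' @param results an [AssociationResult-class].
#' @param threshold LOD cutoff (default 3, approximately p = 2e-4 on one
#'   degree of freedom).
#' @return the updated [AssociationResult-class].
#' @export
callSignificant <- function(results, threshold = 3) {
  stopifnot(is(results, "AssociationResult"))
  tab <- results@table
  tab$significant <- tab$lod >= threshold
  initialize(results, table = tab, threshold = threshold)
}

#' @describeIn associationTable method for AssociationResult
#' @export
setMethod("associationTable", "AssociationResult", function(x) x@table)

#' @describeIn significantSnps method for AssociationResult
#' @export
setMethod("significantSnps", "AssociationResult",
          function(x) x@table[x@table$significant, , drop = FALSE])

setMethod("show", "AssociationResult", function(object) {
  tab <- object@table
  cat(sprintf("AssociationResult: %d tested SNP(s), %d significant at LOD >= %g\n",
              nrow(tab), sum(tab$significant), object@threshold))
  if (length(object@stageSizes))
    cat("  stage sizes:",
        paste(names(object@stageSizes), unlist(object@stageSizes),
              sep = "=", collapse = ", "), "\n")
  if (nrow(tab)) {
    show_n <- min(nrow(tab), 6L)
    print(utils::head(tab[order(-tab$lod), ], show_n), row.names = FALSE)
  }
  invisible(object)
})
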