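# Entropy / mutual-information estimation between a discrete genotype and a
# histogram-discretized phenotype. Natural logs throughout: only the ranking
# of per-SNP scores matters for screening and that is base-invariant.

#' Shannon entropy of a probability vector (nats)
#'
#' \eqn{H = -\sum_x p(x) \log p(x)} with the convention
#' \eqn{0 \cdot \log 0 = 0}.
#'
#' @param p numeric probabilities, non-negative, summing to 1 (tolerance
#'   1e-9).
#' @return entropy in nats.
#' @examples
#' entropyNats(c(0.5, 0.5))  # log(2)
#' @export
entropyNats <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

#' Empirical joint distribution of a genotype column and a binned phenotype
#'
#' Discretizes the phenotype into `bins` equal-width intervals over its
#' observed range (the right-closed histogram rule; the maximum falls in the
#' last bin) and cross-tabulates against the observed genotype states.
#'
#' @param x genotype column (codes in \{1, 0, -1\}, but any discrete vector
#'   works).
#' @param y numeric phenotype of the same length.
#' @param bins number of equal-width phenotype bins, >= 2.
#' @param smoothing optional Laplace pseudo-count added to every cell
#'   (default 0, no smoothing).
#' @return a [JointDistribution-class].
#' @export
jointDistribution <- function(x, y, bins = max(2L, round(sqrt(length(y)))),
                              smoothing = 0) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (bins < 2) stop("bins must be at least 2")
  yb <- .binEqualWidth(as.numeric(y), bins)
  cts <- table(factor(x), factor(yb, levels = seq_len(bins)))
  cts <- matrix(as.numeric(cts), nrow = nrow(cts),
                dimnames = dimnames(cts))
  if (smoothing > 0) cts <- cts + smoothing
  new("JointDistribution", counts = cts, nObs = sum(cts))
}

.binEqualWidth <- function(y, bins) {
  rng <- range(y)
  if (rng[1] == rng[2]) return(rep(1L, length(y)))
  b <- floor((y - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(b, bins)
}

#' Mutual information of a joint table (nats)
#'
#' Two algebraically identical routes are provided: the entropy
#' decomposition \eqn{I = H(X) + H(Y) - H(X,Y)} (default) and the direct
#' double sum \eqn{\sum_{x,y} p(x,y) \log\frac{p(x,y)}{p(x)p(y)}}. Empty
#' cells contribute zero by the \eqn{0 \log 0 = 0} convention.
#'
#' @param joint a [JointDistribution-class], or a count matrix.
#' @param method `"entropy"` or `"direct"`.
#' @return mutual information in nats (non-negative up to rounding).
#' @export
mutualInformation <- function(joint, method = c("entropy", "direct")) {
  method <- match.arg(method)
  cts <- if (is(joint, "JointDistribution")) joint@counts else as.matrix(joint)
  pj <- cts / sum(cts)
  px <- rowSums(pj)
  py <- colSums(pj)
  if (method == "entropy")
    return(entropyNats(px) + entropyNats(py) - entropyNats(as.vector(pj)))
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (outer(px, py)[nz])))
}

#' Mutual information between one SNP and the phenotype
#'
#' Discretizes the (corrected) phenotype into equal-width bins
#' (default `round(sqrt(n))`), builds the joint table against the genotype
#' states and returns the mutual information in nats. A constant phenotype
#' or a constant genotype column carries no information and returns 0.
#'
#' @param x genotype column.
#' @param yPrime numeric phenotype (typically the fixed-effect-corrected
#'   trait).
#' @param bins phenotype bin count, >= 2.
#' @param smoothing Laplace pseudo-count per cell (default 0).
#' @return mutual information in nats.
#' @export
snpPhenotypeMI <- function(x, yPrime,
                           bins = max(2L, round(sqrt(length(yPrime)))),
                           smoothing = 0) {
  yv <- as.numeric(yPrime)
  if (length(x) != length(yv)) stop("x and yPrime must have equal length")
  if (bins < 2) stop("bins must be at least 2")
  if (length(unique(yv)) == 1L) {
    warning("constant phenotype: mutual information is 0")
    return(0)
  }
  if (length(unique(x)) == 1L) return(0)
  mutualInformation(jointDistribution(x, yv, bins, smoothing))
}

#' Mutual-information scores for a whole panel
#'
#' Vectorized computation of [snpPhenotypeMI()] for every SNP column against
#' one phenotype binning, used by the screening stage.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @param yPrime numeric phenotype.
#' @param bins phenotype bin count.
#' @param smoothing Laplace pseudo-count per cell.
#' @return numeric vector of per-SNP MI scores (nats).
#' @export
miScores <- function(G, yPrime,
                     bins = max(2L, round(sqrt(length(yPrime)))),
                     smoothing = 0) {
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  yv <- as.numeric(yPrime)
  n <- nrow(X); p <- ncol(X)
  if (length(yv) != n) stop("phenotype length must equal the individual count")
  if (length(unique(yv)) == 1L) {
    warning("constant phenotype: all mutual-information scores are 0")
    return(numeric(p))
  }
  yb <- .binEqualWidth(yv, bins)
  Y <- matrix(0, n, bins)
  Y[cbind(seq_len(n), yb)] <- 1
  states <- .GENO_CODES
  C <- lapply(states, function(g) crossprod(X == g, Y))  # each p x bins
  if (smoothing > 0) C <- lapply(C, function(M) M + smoothing)
  colTot <- Reduce(`+`, C)              # p x bins phenotype-bin marginals
  nTot <- rowSums(colTot)               # per-SNP total (n, + smoothing mass)
  # I_i = (1/n) sum_cells c (log c - log rowTot - log colTot) + log n
  acc <- numeric(p)
  for (Cs in C) {
    rowTot <- rowSums(Cs)               # per-SNP count of this genotype state
    nz <- Cs > 0
    Tm <- matrix(0, p, bins)
    Tm[nz] <- Cs[nz] * (log(Cs[nz]) - log(colTot[nz]))
    acc <- acc + rowSums(Tm) -
      ifelse(rowTot > 0, rowTot * log(rowTot), 0)
  }
  as.numeric(acc / nTot + log(nTot))
}
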