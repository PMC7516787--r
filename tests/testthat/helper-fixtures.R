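# Shared fixture builders; everything is generated in code at test time.

# Hardy-Weinberg genotype column(s) as a plain matrix.
hweMatrix <- function(n, p, f = 0.3) {
  h <- function() matrix(rbinom(n * p, 1, f), n, p)
  (h() + h()) - 1
}

# A trait with one additive QTN of a given heritability on column `qtn`.
singleQtnTrait <- function(X, qtn, h2, sigma2e = 10, mu = 10) {
  vx <- stats::var(X[, qtn])
  b <- sqrt(h2 / (1 - h2) * sigma2e / vx)
  list(y = mu + b * X[, qtn] + rnorm(nrow(X), 0, sqrt(sigma2e)), b = b)
}

# Orthonormal-in-the-solver-sense design: columns mean 0, population sd 1,
# mutually orthogonal (so crossprod(X) = n * I).
orthonormalDesign <- function() {
  x1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  x2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  cbind(x1, x2)
}

# Brute-force 1-D SCAD minimizer: coarse grid then local refinement of
# 0.5 * (b - z)^2 + rho_{lambda,gamma}(|b|).
scadOracle1d <- function(z, lambda, gamma) {
  obj <- function(b) 0.5 * (b - z)^2 +
    ifelse(b == 0, 0, scadPenalty(b, lambda, gamma))
  grid <- seq(-abs(z) - 1, abs(z) + 1, length.out = 4001)
  i <- which.min(vapply(grid, obj, numeric(1)))
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  # zero is a kink; compare against it explicitly
  if (obj(0) < opt$objective) 0 else opt$minimum
}

# Maximized Gaussian log-likelihood of y on [1, X], sigma^2 profiled out;
# the independent OLS oracle for the likelihood-ratio test.
olsLogLikOracle <- function(y, X = NULL) {
  n <- length(y)
  D <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  rss <- sum(qr.resid(qr(D), y)^2)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# Random joint count table with at least one positive cell.
randomJointTable <- function(nr = 3, nc = 4) {
  m <- matrix(rpois(nr * nc, 3), nr, nc)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}
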