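#' Validate and construct a GenotypeMatrix
#'
#' Checks that a raw integer matrix uses the additive coding \{1, 0, -1\}
#' (homozygotes 1 and -1, heterozygote 0) and that the SNP map matches the
#' panel. Missing values are rejected unless `impute = TRUE`, in which case
#' each `NA` is filled with its column's modal code before validation.
#'
#' @param raw numeric/integer matrix, individuals in rows, SNPs in columns.
#' @param map `data.frame` with columns `snp_id`, `chrom`, `pos` (one row per
#'   SNP column). If omitted, a synthetic single-chromosome map with positions
#'   `1:p` is created.
#' @param impute fill missing genotype calls with the column mode
#'   (ties broken in favour of the heterozygote 0, then -1, then 1).
#' @return a validated [GenotypeMatrix-class].
#' @examples
#' G <- validateGenotypes(rbind(c(1, 0), c(-1, 1)))
#' nIndividuals(G); nSnps(G)
#' @export
validateGenotypes <- function(raw, map = NULL, impute = FALSE) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (anyNA(raw)) {
    if (!impute)
      stop("genotype matrix contains missing calls; set impute = TRUE for column-mode fill")
    raw <- imputeMode(raw)
  }
  bad <- which(!(raw %in% .GENO_CODES))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(raw)) + 1L
    stop(sprintf("invalid genotype code %s at row %d, column %d (allowed: 1, 0, -1)",
                 format(raw[bad[1]]), i, j))
  }
  if (is.null(map)) {
    ids <- colnames(raw)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(ncol(raw)))
    map <- data.frame(snp_id = ids, chrom = 1L, pos = seq_len(ncol(raw)),
                      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(map)) map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map) != ncol(raw))
    stop(sprintf("SNP map has %d rows but the genotype matrix has %d columns",
                 nrow(map), ncol(raw)))
  names(map)[1:3] <- c("snp_id", "chrom", "pos")
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.numeric(map$pos)
  new("GenotypeMatrix", X = raw, snpMap = map)
}

#' Impute missing genotype calls to the column mode
#'
#' @param raw genotype matrix possibly containing `NA`; non-missing entries
#'   must already use the \{1, 0, -1\} coding.
#' @return the matrix with each `NA` replaced by its column's most frequent
#'   code (ties broken 0, then -1, then 1).
#' @export
imputeMode <- function(raw) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  order_pref <- c(0, -1, 1)
  for (j in seq_len(ncol(raw))) {
    miss <- is.na(raw[, j])
    if (!any(miss)) next
    obs <- raw[!miss, j]
    if (!length(obs))
      stop(sprintf("column %d is entirely missing; cannot impute", j))
    cnt <- vapply(order_pref, function(v) sum(obs == v), numeric(1))
    raw[miss, j] <- order_pref[which.max(cnt)]
  }
  raw
}

#' @describeIn genotypes method for GenotypeMatrix
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@X)

#' @describeIn snpMap method for GenotypeMatrix
#' @export
setMethod("snpMap", "GenotypeMatrix", function(x) x@snpMap)

#' @describeIn nIndividuals method for GenotypeMatrix
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@X))

#' @describeIn nSnps method for GenotypeMatrix
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@X))

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@X))

#' Subset a GenotypeMatrix
#'
#' `x[i, j]` keeps individuals `i` and SNPs `j`; the SNP map is subset in
#' step with the columns.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i,j individual and SNP indices.
#' @param ... ignored.
#' @param drop ignored (result is always a GenotypeMatrix).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (missing(j)) j <- seq_len(ncol(x@X))
  new("GenotypeMatrix", X = x@X[i, j, drop = FALSE],
      snpMap = x@snpMap[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(object@X), ncol(object@X),
              length(unique(object@snpMap$chrom))))
  f <- alleleFrequencies(object)
  if (length(f))
    cat(sprintf("  allele frequency range: %.3f - %.3f\n", min(f), max(f)))
  invisible(object)
})

#' Per-SNP allele frequency under the additive coding
#'
#' Frequency of the allele counted by the +1 homozygote:
#' `(2 #\{+1\} + #\{0\}) / (2 n)`.
#'
#' @param G a [GenotypeMatrix-class] or coded matrix.
#' @return numeric vector of length p.
#' @export
alleleFrequencies <- function(G) {
  X <- if (is(G, "GenotypeMatrix")) G@X else as.matrix(G)
  (2 * colSums(X == 1) + colSums(X == 0)) / (2 * nrow(X))
}
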