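# Delimited-text readers and writers. All readers tolerate '#' comment lines.

#' Read a genotype panel from delimited text
#'
#' The genotype file is whitespace/tab-delimited with a header row of SNP
#' identifiers and one row per individual; an optional first column named
#' `id` carries individual identifiers. The map file has three columns
#' (`snp_id`, `chrom`, `pos`) with a header. Lines starting with `#` are
#' ignored in both files.
#'
#' @param genoFile path to the genotype table.
#' @param mapFile path to the SNP map; if `NULL` a synthetic map is created.
#' @param impute passed to [validateGenotypes()].
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(genoFile, mapFile = NULL, impute = FALSE) {
  tab <- read.table(genoFile, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- NULL
  if (names(tab)[1] %in% c("id", "ID", "iid", "IID")) {
    ids <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  X <- as.matrix(tab)
  rownames(X) <- ids
  map <- NULL
  if (!is.null(mapFile)) {
    map <- read.table(mapFile, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(map) < 3) stop("SNP map must have columns snp_id, chrom, pos")
  }
  validateGenotypes(X, map, impute = impute)
}

#' Write a genotype panel to delimited text
#'
#' Writes the tab-delimited genotype table (header = SNP ids, first column
#' `id`) and the three-column SNP map. [readGenotypes()] on the two files
#' reproduces the object exactly.
#'
#' @param G a [GenotypeMatrix-class].
#' @param genoFile,mapFile output paths.
#' @return invisibly, the two paths.
#' @export
writeGenotypes <- function(G, genoFile, mapFile) {
  stopifnot(is(G, "GenotypeMatrix"))
  X <- G@X
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(X)))
  tab <- data.frame(id = ids, X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("id", G@snpMap$snp_id)
  write.table(tab, genoFile, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(G@snpMap, mapFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genoFile, mapFile))
}

#' Read a phenotype from two-column delimited text
#'
#' Expects columns `(individual_id, value)` with a header; `#` comment lines
#' are skipped. Non-numeric or `NA` markers are read as missing (handle with
#' [dropMissingPhenotype()]).
#'
#' @param file path.
#' @return named numeric vector (possibly with `NA`), names = individual ids.
#' @export
readPhenotype <- function(file) {
  tab <- read.table(file, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  if (ncol(tab) < 2) stop("phenotype file must have columns (individual_id, value)")
  y <- as.numeric(tab[[2]])
  names(y) <- as.character(tab[[1]])
  y
}

#' Read a fixed-effect covariate matrix
#'
#' Whitespace-delimited numeric table, `n` rows by `q` columns, optional
#' header, `#` comments tolerated.
#'
#' @param file path.
#' @param header logical; does the file carry a header row?
#' @return a [FixedEffects-class].
#' @export
readCovariates <- function(file, header = TRUE) {
  tab <- read.table(file, header = header, comment.char = "#")
  fixedEffects(as.matrix(tab))
}

#' Read a PLINK additive-dosage (.raw) file
#'
#' Ingests the text output of `plink --recode A`: columns FID IID PAT MAT
#' SEX PHENOTYPE followed by one 0/1/2 minor-allele dosage column per SNP.
#' Dosages are recoded to the package's \{1, 0, -1\} convention
#' (2 -> 1, 1 -> 0, 0 -> -1). `.raw` files carry no positions, so either
#' supply a map file or accept a synthetic single-chromosome map.
#'
#' @param rawFile path to the `.raw` file.
#' @param mapFile optional three-column SNP map (`snp_id`, `chrom`, `pos`).
#' @param impute passed to [validateGenotypes()] (missing dosages `NA`).
#' @return a [GenotypeMatrix-class].
#' @export
readPlinkRaw <- function(rawFile, mapFile = NULL, impute = FALSE) {
  tab <- read.table(rawFile, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  keep <- !(toupper(names(tab)) %in% meta)
  ids <- if ("IID" %in% toupper(names(tab))) {
    as.character(tab[[which(toupper(names(tab)) == "IID")[1]]])
  } else NULL
  X <- as.matrix(tab[, keep, drop = FALSE])
  if (!all(X %in% c(0, 1, 2, NA)))
    stop("PLINK .raw dosages must be 0, 1, 2 or NA")
  X <- X - 1
  rownames(X) <- ids
  # strip the _<allele> suffix plink appends to SNP ids
  colnames(X) <- sub("_[ACGT0-9]+$", "", colnames(X))
  map <- NULL
  if (!is.null(mapFile))
    map <- read.table(mapFile, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  validateGenotypes(X, map, impute = impute)
}

#' Serialize a screening result to delimited text
#'
#' One row per SNP: `snp_id`, `measure`, `score`, `type`
#' (`I`, `II` or `-`) and `selected` flag.
#'
#' @param x a [ScreenResult-class].
#' @param map SNP map (`data.frame` with `snp_id`) or [GenotypeMatrix-class].
#' @param file output path.
#' @return invisibly, the written `data.frame`.
#' @export
writeScreenResult <- function(x, map, file) {
  stopifnot(is(x, "ScreenResult"))
  if (is(map, "GenotypeMatrix")) map <- snpMap(map)
  p <- length(x@scores)
  type <- rep("-", p)
  type[x@typeI] <- "I"
  type[x@typeII] <- "II"
  tab <- data.frame(snp_id = map$snp_id, measure = x@measure,
                    score = x@scores, type = type,
                    selected = type != "-", stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write the final association table
#'
#' Tab-delimited columns `snp_id`, `chrom`, `pos`, `effect`, `lod`,
#' `p_value`, `significant` -- a minimal GWAS summary-statistics layout.
#'
#' @param x an [AssociationResult-class].
#' @param file output path.
#' @return invisibly, the table.
#' @export
writeAssociation <- function(x, file) {
  stopifnot(is(x, "AssociationResult"))
  write.table(x@table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x@table)
}

#' Serialize an EM Bayesian Lasso fit
#'
#' @param fit an [EmBlassoFit-class].
#' @param snpIds SNP identifiers for the fitted columns.
#' @param file output path.
#' @return invisibly, the written table (`snp_id`, `effect`, `retained`).
#' @export
writeEmBlassoFit <- function(fit, snpIds, file) {
  stopifnot(is(fit, "EmBlassoFit"))
  tab <- data.frame(snp_id = snpIds, effect = fit@beta,
                    retained = seq_along(fit@beta) %in% fit@retained,
                    stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
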