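# Accessor generics shared across the package's classes.

#' Extract the genotype code matrix
#' @param x a [GenotypeMatrix-class].
#' @return numeric matrix, individuals x SNPs, entries in \{1, 0, -1\}.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Extract the SNP map
#' @param x a [GenotypeMatrix-class].
#' @return `data.frame` with columns `snp_id`, `chrom`, `pos`.
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' Number of individuals
#' @param x a [GenotypeMatrix-class].
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Number of SNPs
#' @param x a [GenotypeMatrix-class].
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Marginal screening scores
#' @param x a [ScreenResult-class].
#' @export
setGeneric("screenScores", function(x) standardGeneric("screenScores"))

#' Type I SNP set (first-pass SIS-SCAD survivors)
#' @param x a [ScreenResult-class].
#' @export
setGeneric("typeISet", function(x) standardGeneric("typeISet"))

#' Type II SNP set (SNPs revived by the single ISIS iteration)
#' @param x a [ScreenResult-class].
#' @export
setGeneric("typeIISet", function(x) standardGeneric("typeIISet"))

#' Union of the Type I and Type II sets
#' @param x a [ScreenResult-class].
#' @export
setGeneric("unionSet", function(x) standardGeneric("unionSet"))

#' Retained effect indices of a shrinkage fit
#' @param x an [EmBlassoFit-class].
#' @export
setGeneric("retainedSet", function(x) standardGeneric("retainedSet"))

#' Final association table
#' @param x an [AssociationResult-class].
#' @export
setGeneric("associationTable", function(x) standardGeneric("associationTable"))

#' Rows of the association table called significant
#' @param x an [AssociationResult-class].
#' @export
setGeneric("significantSnps", function(x) standardGeneric("significantSnps"))
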