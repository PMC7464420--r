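#' Breed labels of a genotype panel
#'
#' @param x A \linkS4class{GenotypePanel}.
#' @return Character vector, one breed label per individual (in `colnames(x)`
#'   order).
#' @export
setGeneric("breeds", function(x) standardGeneric("breeds"))

#' SNP identifiers
#'
#' @param x A \linkS4class{GenotypePanel} or \linkS4class{AlleleCounts}.
#' @return Character vector of marker names, one per locus.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Genotype call matrix
#'
#' @param x A \linkS4class{GenotypePanel}.
#' @return Integer matrix (loci x individuals) counting copies of the A
#'   allele; `NA` marks missing calls.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' A/B allele labels
#'
#' @param x A \linkS4class{GenotypePanel}.
#' @return Two-column character matrix (`A`, `B`), one row per locus; `NA`
#'   where an allele was never observed.
#' @export
setGeneric("alleleLabels", function(x) standardGeneric("alleleLabels"))

#' Allele count matrices
#'
#' @param x An \linkS4class{AlleleCounts} object.
#' @return Integer matrix (loci x populations): `countsA` returns A-allele
#'   counts, `countsTotal` the number of successfully called alleles
#'   (2 x non-missing genotypes).
#' @export
setGeneric("countsA", function(x) standardGeneric("countsA"))

#' @rdname countsA
#' @export
setGeneric("countsTotal", function(x) standardGeneric("countsTotal"))
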