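#' @include AllGenerics.R
NULL

#' greyscan: multi-cohort FST-outlier selection-signature scans
#'
#' Core containers. Loci live in rows (Bioconductor convention), individuals
#' or populations in columns. Coordinates are 1-based inclusive throughout.
#'
#' @import methods
#' @importFrom stats rbeta rbinom rnorm runif setNames
#' @importFrom utils read.table write.table
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowRanges rowData colData
#' @importMethodsFrom S4Vectors mcols "mcols<-"
#' @useDynLib greyscan, .registration = TRUE
#' @name greyscan-package
"_PACKAGE"

#' Biallelic SNP-array genotype panel with breed labels
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay, `"calls"`:
#' an integer matrix (loci x individuals) counting copies of the per-locus A
#' allele (0, 1, 2), with `NA` for missing genotypes. `rowRanges` carry the
#' map (chromosome, 1-based physical position, width-1 ranges, names =
#' SNP ids) plus `alleleA`/`alleleB` metadata columns; `colData` carries the
#' breed label and within-breed individual id.
#'
#' The A allele is an arbitrary per-locus orientation (first allele character
#' seen in the source file). The F-model likelihood is symmetric under
#' relabeling A and B, so downstream results do not depend on it.
#'
#' @aliases GenotypePanel-class
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        calls <- SummarizedExperiment::assay(object, "calls")
        bad <- calls[!is.na(calls)]
        if (length(bad) && !all(bad %in% 0:2))
            msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"breed" %in% colnames(cd))
        msg <- c(msg, "colData column 'breed' is required")
    else if (any(is.na(cd$breed) | !nzchar(cd$breed)))
        msg <- c(msg, "every individual needs a non-empty breed label")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("alleleA", "alleleB") %in% colnames(rd)))
        msg <- c(msg, "rowData columns 'alleleA' and 'alleleB' are required")
    ids <- rownames(object)
    if (is.null(ids) && nrow(object) > 0)
        msg <- c(msg, "loci must be named by SNP id")
    if (!is.null(ids) && anyDuplicated(ids))
        msg <- c(msg, "SNP ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls Integer matrix (loci x individuals) of A-allele dosages with
#'   `NA` for missing; rownames are SNP ids.
#' @param chrom Character vector of chromosome labels, one per locus.
#' @param position_bp Integer vector of 1-based physical positions.
#' @param breed Character vector of breed labels, one per individual.
#' @param indiv_id Individual identifiers; defaults to `colnames(calls)`.
#' @param alleleA,alleleB Per-locus allele characters (may be `NA`).
#' @return A \linkS4class{GenotypePanel}.
#' @examples
#' gp <- GenotypePanel(
#'   calls = matrix(c(2L, 1L, 0L, NA), 2, 2,
#'                  dimnames = list(c("snp1", "snp2"), c("i1", "i2"))),
#'   chrom = c("14", "14"), position_bp = c(100L, 200L),
#'   breed = c("Maremmana", "Angus"),
#'   alleleA = c("A", "G"), alleleB = c("G", "T"))
#' breeds(gp)
#' @export
GenotypePanel <- function(calls, chrom, position_bp, breed,
                          indiv_id = colnames(calls),
                          alleleA = NA_character_, alleleB = NA_character_) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    n_loci <- nrow(calls)
    if (is.null(rownames(calls)) && n_loci > 0)
        stop("'calls' must have SNP ids as rownames")
    if (is.null(indiv_id))
        indiv_id <- paste0("ind", seq_len(ncol(calls)))
    colnames(calls) <- make.unique(paste(breed, indiv_id, sep = "_"))
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(chrom),
        ranges = IRanges::IRanges(start = as.integer(position_bp), width = 1L),
        alleleA = rep_len(as.character(alleleA), n_loci),
        alleleB = rep_len(as.character(alleleB), n_loci))
    names(rr) <- rownames(calls)
    cd <- S4Vectors::DataFrame(breed = as.character(breed),
                               indiv_id = as.character(indiv_id),
                               row.names = colnames(calls))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls), rowRanges = rr, colData = cd)
    methods::new("GenotypePanel", se)
}

#' Per-population allele count table
#'
#' A \linkS4class{RangedSummarizedExperiment} with assays `a` (A-allele
#' counts) and `n` (total called alleles, always even), loci in rows and
#' populations in columns. These are the sufficient statistics of the
#' beta-binomial F-model likelihood.
#'
#' @aliases AlleleCounts-class
#' @export
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

setValidity("AlleleCounts", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("a", "n") %in% an))
        return("assays 'a' and 'n' are required")
    a <- SummarizedExperiment::assay(object, "a")
    n <- SummarizedExperiment::assay(object, "n")
    if (any(a < 0) || any(n < 0) || any(a > n))
        msg <- c(msg, "counts must satisfy 0 <= a <= n")
    if (any(n %% 2L != 0L))
        msg <- c(msg, "'n' must be even (two called alleles per genotype)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypePanel", function(object) {
    cat(sprintf("GenotypePanel: %d loci x %d individuals (%d breeds)\n",
                nrow(object), ncol(object),
                length(unique(object$breed))))
    calls <- SummarizedExperiment::assay(object, "calls")
    miss <- if (length(calls)) mean(is.na(calls)) else 0
    cat(sprintf("  missing call rate: %.3f\n", miss))
    br <- table(object$breed)
    cat("  breeds:", paste(sprintf("%s(%d)", names(br), br), collapse = ", "),
        "\n")
})

setMethod("show", "AlleleCounts", function(object) {
    cat(sprintf("AlleleCounts: %d loci x %d populations (%s)\n",
                nrow(object), ncol(object),
                paste(colnames(object), collapse = ", ")))
})

#' @rdname breeds
setMethod("breeds", "GenotypePanel", function(x) x$breed)

#' @rdname snpIds
setMethod("snpIds", "GenotypePanel", function(x) rownames(x))

#' @rdname snpIds
setMethod("snpIds", "AlleleCounts", function(x) rownames(x))

#' @rdname genotypeCalls
setMethod("genotypeCalls", "GenotypePanel",
          function(x) SummarizedExperiment::assay(x, "calls"))

#' @rdname alleleLabels
setMethod("alleleLabels", "GenotypePanel", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    cbind(A = rd$alleleA, B = rd$alleleB)
})

#' @rdname countsA
setMethod("countsA", "AlleleCounts",
          function(x) SummarizedExperiment::assay(x, "a"))

#' @rdname countsA
setMethod("countsTotal", "AlleleCounts",
          function(x) SummarizedExperiment::assay(x, "n"))
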