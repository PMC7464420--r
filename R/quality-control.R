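#' Quality-control configuration
#'
#' Thresholds follow the PLINK commands used for medium-density bovine
#' SNP-array panels: `--geno 0.1` (drop loci whose missing-call fraction
#' exceeds 0.1), `--mind 0.1` (same per individual), `--maf 0.01` (drop loci
#' with minor allele frequency below 0.01), and restriction to the 29 bovine
#' autosomes. The removal rules are the commands' operational semantics:
#' missingness strictly greater than the threshold removes; MAF greater than
#' or equal to the threshold keeps.
#'
#' @param max_locus_missing Maximum tolerated missing fraction per locus.
#' @param max_indiv_missing Maximum tolerated missing fraction per individual.
#' @param min_maf Minimum minor allele frequency kept.
#' @param autosomes Character vector of autosomal chromosome labels.
#' @return A list of class `qc_control`.
#' @export
qcControl <- function(max_locus_missing = 0.1, max_indiv_missing = 0.1,
                      min_maf = 0.01, autosomes = as.character(1:29)) {
    stopifnot(max_locus_missing >= 0, max_locus_missing <= 1,
              max_indiv_missing >= 0, max_indiv_missing <= 1,
              min_maf >= 0, min_maf <= 1)
    structure(list(max_locus_missing = max_locus_missing,
                   max_indiv_missing = max_indiv_missing,
                   min_maf = min_maf,
                   autosomes = as.character(autosomes)),
              class = "qc_control")
}

#' Drop non-autosomal loci
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param autosomes Chromosome labels to keep.
#' @return The panel restricted to autosomal loci, order preserved.
#' @export
filterNonAutosomal <- function(panel, autosomes = as.character(1:29)) {
    chrom <- as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(panel)))
    panel[chrom %in% as.character(autosomes), ]
}

#' Drop individuals with excess missingness
#'
#' An individual is removed when its fraction of missing calls strictly
#' exceeds `max_indiv_missing` (PLINK `--mind` semantics: exactly at the
#' threshold is kept).
#'
#' @param panel A \linkS4class{GenotypePanel} with at least one locus.
#' @param max_indiv_missing Missingness threshold.
#' @return The panel restricted to passing individuals.
#' @export
filterIndividuals <- function(panel, max_indiv_missing = 0.1) {
    if (nrow(panel) == 0L) return(panel)
    miss <- colMeans(is.na(genotypeCalls(panel)))
    panel[, miss <= max_indiv_missing]
}

#' Drop loci with excess missingness
#'
#' A locus is removed when its missing-call fraction strictly exceeds
#' `max_locus_missing` (PLINK `--geno` semantics).
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param max_locus_missing Missingness threshold.
#' @return The panel restricted to passing loci.
#' @export
filterLociCallRate <- function(panel, max_locus_missing = 0.1) {
    if (ncol(panel) == 0L) return(panel)
    miss <- rowMeans(is.na(genotypeCalls(panel)))
    panel[miss <= max_locus_missing, ]
}

#' Minor allele frequencies of a panel
#'
#' Computed on non-missing calls across all current individuals. Loci with
#' no called genotypes get MAF 0.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @return Numeric vector in `[0, 0.5]`, one value per locus.
#' @export
minorAlleleFreq <- function(panel) {
    calls <- genotypeCalls(panel)
    n <- 2 * rowSums(!is.na(calls))
    a <- rowSums(calls, na.rm = TRUE)
    p <- ifelse(n > 0, a / n, 0)
    pmin(p, 1 - p)
}

#' Drop low-MAF loci
#'
#' Loci are kept when MAF is greater than or equal to `min_maf` (PLINK
#' `--maf` semantics); monomorphic loci are always removed for
#' `min_maf > 0`.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param min_maf MAF threshold.
#' @return The panel restricted to passing loci.
#' @export
filterMAF <- function(panel, min_maf = 0.01) {
    panel[minorAlleleFreq(panel) >= min_maf, ]
}

#' Run the full QC cascade
#'
#' Applies, in order: autosome restriction, individual missingness
#' (`--mind`), locus call rate (`--geno`), minor allele frequency (`--maf`).
#' Individuals are filtered before the locus statistics, matching the PLINK
#' processing order, so call rate and MAF are computed on the retained
#' individual set.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param control A [qcControl()] list.
#' @return A list with elements `panel` (the filtered
#'   \linkS4class{GenotypePanel}) and `report` (a one-row data.frame of
#'   per-stage removal counts; kept + removed reconstructs the input totals).
#' @export
runQC <- function(panel, control = qcControl()) {
    n_loci0 <- nrow(panel)
    n_ind0 <- ncol(panel)

    p1 <- filterNonAutosomal(panel, control$autosomes)
    n_nonauto <- n_loci0 - nrow(p1)
    p2 <- filterIndividuals(p1, control$max_indiv_missing)
    n_ind_rm <- ncol(p1) - ncol(p2)
    p3 <- filterLociCallRate(p2, control$max_locus_missing)
    n_callrate <- nrow(p2) - nrow(p3)
    p4 <- filterMAF(p3, control$min_maf)
    n_maf <- nrow(p3) - nrow(p4)

    if (nrow(p4) == 0L || ncol(p4) == 0L)
        stop("all data filtered: no loci or individuals survive QC")

    report <- data.frame(
        n_individuals_in = n_ind0,
        n_individuals_removed = n_ind_rm,
        n_individuals_kept = ncol(p4),
        n_loci_in = n_loci0,
        n_loci_removed_nonautosomal = n_nonauto,
        n_loci_removed_call_rate = n_callrate,
        n_loci_removed_maf = n_maf,
        n_loci_kept = nrow(p4))
    list(panel = p4, report = report)
}
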