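# Shared fixture builders; everything is generated in code at test time.

# AlleleCounts from bare matrices (loci x 2 populations)
mk_counts <- function(a, n, pops = c("P1", "P2")) {
    a <- as.matrix(a); n <- as.matrix(n)
    if (is.null(rownames(a)))
        rownames(a) <- paste0("L", seq_len(nrow(a)))
    rownames(n) <- rownames(a)
    colnames(a) <- colnames(n) <- pops
    rr <- GenomicRanges::GRanges(rep("1", nrow(a)),
                                 IRanges::IRanges(seq_len(nrow(a)),
                                                  width = 1))
    names(rr) <- rownames(a)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(a = a, n = n), rowRanges = rr)
    methods::new("AlleleCounts", se)
}

# small panel from an explicit call matrix
mk_panel <- function(calls, chrom = rep("1", nrow(calls)),
                     pos = seq_len(nrow(calls)) * 1000L,
                     breed = rep("B1", ncol(calls))) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(rownames(calls)) && nrow(calls) > 0)
        rownames(calls) <- paste0("snp", seq_len(nrow(calls)))
    GenotypePanel(calls = calls, chrom = chrom, position_bp = pos,
                  breed = breed, indiv_id = paste0("i", seq_len(ncol(calls))),
                  alleleA = "A", alleleB = "G")
}

# write a PED/MAP pair into a temp dir; returns the two paths
write_ped_fixture <- function(ped_lines, map_lines, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
    ped <- file.path(dir, "panel.ped")
    map <- file.path(dir, "panel.map")
    writeLines(ped_lines, ped)
    writeLines(map_lines, map)
    list(ped = ped, map = map)
}

# short MCMC settings for unit-scale scans
quick_mcmc <- function(seed = 1L, ...)
    mcmcControl(n_pilot = 5L, pilot_length = 200L, burn_in = 800L,
                n_samples = 600L, thinning = 4L, seed = seed, ...)

# the packaged study design fixture
design_fixture <- function() {
    path <- system.file("extdata", "grey_breed_design.tsv",
                        package = "greyscan")
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# the packaged candidate-SNP report fixture
candidate_fixture <- function() {
    path <- system.file("extdata", "grey_candidate_snps.tsv",
                        package = "greyscan")
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE)
}
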