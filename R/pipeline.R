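#' Pipeline configuration
#'
#' Bundles every stage's settings with the study defaults: q-value
#' threshold 0.05, occurrence threshold 15 contrasts (25\% of 60), window
#' half-width 250 kbp.
#'
#' @param ped,map Paths to the genotype PED/MAP files.
#' @param design Path to a breed-design TSV (see [readContrastDesign()]).
#' @param annotation Optional path to a BED/GFF3 gene annotation.
#' @param outdir Output directory.
#' @param qc A [qcControl()] list.
#' @param mcmc An [mcmcControl()] list.
#' @param q_threshold Per-pair q-value retention threshold.
#' @param min_count Absolute occurrence threshold; `NULL` to use
#'   `min_fraction`.
#' @param min_fraction Fractional occurrence threshold alternative.
#' @param half_width Window flank in bp.
#' @return A list of class `pipeline_config`.
#' @export
pipelineConfig <- function(ped, map, design, annotation = NULL,
                           outdir = "greyscan-out",
                           qc = qcControl(), mcmc = mcmcControl(),
                           q_threshold = 0.05, min_count = 15L,
                           min_fraction = NULL, half_width = 250000L) {
    structure(list(ped = ped, map = map, design = design,
                   annotation = annotation, outdir = outdir,
                   qc = qc, mcmc = mcmc, q_threshold = q_threshold,
                   min_count = min_count, min_fraction = min_fraction,
                   half_width = half_width),
              class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; `qc` and `mcmc`
#' are nested mappings passed to [qcControl()] and [mcmcControl()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    qc <- do.call(qcControl, y$qc %||% list())
    mc <- do.call(mcmcControl, y$mcmc %||% list())
    y$qc <- NULL; y$mcmc <- NULL
    do.call(pipelineConfig, c(y, list(qc = qc, mcmc = mc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full selection-signature pipeline
#'
#' Orchestrates QC, the per-pair FST-outlier scans, cross-contrast
#' aggregation, window construction and gene annotation, writing four
#' artifacts into `config$outdir`:
#' \itemize{
#'   \item `qc_report.tsv` — per-stage QC survivor counts
#'   \item `posteriors/<grey>__<reference>.tsv` — per-pair locus posteriors
#'   \item `occurrence.tsv` — per-SNP significance occurrence counts
#'   \item `report.tsv` — retained SNPs with windows and gene lists
#' }
#' Per-pair MCMC results are cached under `outdir/cache`, keyed by the
#' pair's data and settings, so rerunning an identical configuration reuses
#' them and reproduces identical outputs.
#'
#' @param config A [pipelineConfig()] list.
#' @param verbose Log per-stage progress.
#' @return Invisibly, a list with `qc_report`, `results`
#'   (`contrast_results`), `occurrence`, `retained` (SNP ids), `report`
#'   (the final table) and `outdir`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    say <- function(...) if (verbose) message(sprintf(...))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

    say("stage 1/5: reading genotypes")
    panel <- readPedMap(config$ped, config$map)
    say("  %d loci x %d individuals", nrow(panel), ncol(panel))

    say("stage 2/5: quality control")
    qc <- runQC(panel, config$qc)
    write.table(qc$report, file.path(config$outdir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("  kept %d loci, %d individuals",
        qc$report$n_loci_kept, qc$report$n_individuals_kept)

    say("stage 3/5: pairwise FST-outlier scans")
    design <- readContrastDesign(config$design)
    results <- runAllContrasts(qc$panel, design, config$mcmc,
                               config$q_threshold,
                               cache_dir = file.path(config$outdir, "cache"),
                               verbose = verbose)
    post_dir <- file.path(config$outdir, "posteriors")
    dir.create(post_dir, showWarnings = FALSE)
    for (k in seq_along(results$posteriors)) {
        pair <- design$pairs[k, ]
        write.table(results$posteriors[[k]],
                    file.path(post_dir, paste0(pair$grey, "__",
                                               pair$reference, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    say("stage 4/5: cross-contrast aggregation")
    occ <- occurrenceTable(results, design)
    write.table(occ, file.path(config$outdir, "occurrence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    retained <- applyOccurrenceThreshold(occ, config$min_count,
                                         config$min_fraction,
                                         loci = qc$panel)
    say("  %d SNPs pass the occurrence threshold", length(retained))

    say("stage 5/5: windows and annotation")
    loci_gr <- SummarizedExperiment::rowRanges(qc$panel)
    windows <- snpWindow(loci_gr[retained], config$half_width)
    genes <- if (!is.null(config$annotation)) {
        readGeneAnnotation(config$annotation)
    } else {
        g <- GenomicRanges::GRanges()
        S4Vectors::mcols(g)$symbol <- character(0)
        g
    }
    annotated <- genesInRegions(windows, genes)
    report <- reportTable(occ, annotated, loci_gr, design,
                          path = file.path(config$outdir, "report.tsv"))
    say("done: artifacts in %s", config$outdir)

    invisible(list(qc_report = qc$report, results = results,
                   occurrence = occ, retained = retained, report = report,
                   outdir = config$outdir))
}
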