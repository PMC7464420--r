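#' Build the grey-by-reference contrast design
#'
#' Forms the full Cartesian product of test ("grey") breeds and reference
#' ("non-grey") breeds, in test-major order: all references for the first
#' test breed, then the second, and so on. The study design contrasts 15
#' grey with 4 non-grey breeds, yielding 60 pairs.
#'
#' @param grey_breeds Character vector of test breed labels.
#' @param reference_breeds Character vector of reference breed labels.
#' @return A list of class `contrast_design` with elements `grey_breeds`,
#'   `reference_breeds` and `pairs` (a data.frame with columns `grey`,
#'   `reference`).
#' @export
buildContrasts <- function(grey_breeds, reference_breeds) {
    grey_breeds <- as.character(grey_breeds)
    reference_breeds <- as.character(reference_breeds)
    if (!length(grey_breeds) || !length(reference_breeds))
        stop("both breed lists must be non-empty")
    overlap <- intersect(grey_breeds, reference_breeds)
    if (length(overlap))
        stop("breed(s) in both lists: ", paste(overlap, collapse = ", "))
    pairs <- data.frame(
        grey = rep(grey_breeds, each = length(reference_breeds)),
        reference = rep(reference_breeds, times = length(grey_breeds)),
        stringsAsFactors = FALSE)
    structure(list(grey_breeds = grey_breeds,
                   reference_breeds = reference_breeds,
                   pairs = pairs),
              class = "contrast_design")
}

#' Read a breed design file
#'
#' Tab-separated file with columns `breed` and `group` (values `grey` /
#' `reference`); an optional `n` column is ignored here. The packaged
#' example design (`system.file("extdata", "grey_breed_design.tsv",
#' package = "greyscan")`) describes the 15 + 4 breed panel of 514 animals.
#'
#' @param path Path to the TSV design file.
#' @return A `contrast_design`, see [buildContrasts()].
#' @export
readContrastDesign <- function(path) {
    d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
    stopifnot(all(c("breed", "group") %in% colnames(d)))
    buildContrasts(d$breed[d$group == "grey"],
                   d$breed[d$group == "reference"])
}

#' Run the outlier scan for every contrast pair
#'
#' For each (grey, reference) pair: subsets the panel to the two breeds,
#' derives allele counts, runs [runFstScan()], and collects the loci
#' significant at `q_threshold`. Each pair gets a distinct deterministic
#' seed derived from `control$seed` and the pair's position in the design.
#'
#' When `cache_dir` is given, per-pair posteriors are cached on disk keyed
#' by a hash of the pair's counts and the MCMC settings, so an interrupted
#' multi-pair run resumes without recomputation.
#'
#' @param panel A \linkS4class{GenotypePanel} (after QC).
#' @param design A `contrast_design` from [buildContrasts()].
#' @param control An [mcmcControl()] list.
#' @param q_threshold q-value retention threshold (strict `<`).
#' @param cache_dir Optional directory for per-pair result caching.
#' @param verbose Print one progress line per pair.
#' @return A list of class `contrast_results`: `significant` (named list,
#'   one character vector of SNP ids per pair, names `"grey|reference"`),
#'   `posteriors` (named list of per-pair scan data.frames), `design`,
#'   `q_threshold`.
#' @export
runAllContrasts <- function(panel, design, control = mcmcControl(),
                            q_threshold = 0.05, cache_dir = NULL,
                            verbose = FALSE) {
    present <- unique(breeds(panel))
    need <- unique(c(design$grey_breeds, design$reference_breeds))
    absent <- setdiff(need, present)
    if (length(absent))
        stop("design breed(s) absent from panel: ",
             paste(absent, collapse = ", "))
    if (!is.null(cache_dir) && !dir.exists(cache_dir))
        dir.create(cache_dir, recursive = TRUE)

    pairs <- design$pairs
    significant <- vector("list", nrow(pairs))
    posteriors <- vector("list", nrow(pairs))
    names(significant) <- names(posteriors) <-
        paste(pairs$grey, pairs$reference, sep = "|")

    for (k in seq_len(nrow(pairs))) {
        pops <- c(pairs$grey[k], pairs$reference[k])
        counts <- alleleCounts(panel, pops)
        ctl <- control
        ctl$seed <- .pair_seed(control$seed, k)
        key <- rlang::hash(list(pops, countsA(counts), countsTotal(counts),
                                unclass(ctl), q_threshold))
        cache_file <- if (!is.null(cache_dir))
            file.path(cache_dir, paste0("pair-", key, ".rds"))
        if (!is.null(cache_file) && file.exists(cache_file)) {
            post <- readRDS(cache_file)
        } else {
            post <- runFstScan(counts, ctl)
            if (!is.null(cache_file)) saveRDS(post, cache_file)
        }
        posteriors[[k]] <- post
        significant[[k]] <- significantLoci(post, q_threshold)
        if (verbose)
            message(sprintf("[%d/%d] %s vs %s: %d significant loci",
                            k, nrow(pairs), pops[1], pops[2],
                            length(significant[[k]])))
    }
    structure(list(significant = significant, posteriors = posteriors,
                   design = design, q_threshold = q_threshold),
              class = "contrast_results")
}

# distinct reproducible sub-seed per pair, kept below 2^31
.pair_seed <- function(master, k) {
    (as.numeric(master) * 7919 + 104729 * as.numeric(k)) %% 2147483647
}

#' Per-SNP occurrence counts of significance across contrasts
#'
#' Tabulates, for every SNP in the panel, in how many contrasts it was
#' significant, broken down by reference breed, plus the overall count (the
#' row sum). Counts are invariant to the order of pairs in the design.
#'
#' @param results A `contrast_results` from [runAllContrasts()].
#' @param design Optionally, the design (defaults to `results$design`).
#' @return A data.frame with columns `snp_id`, one count column per
#'   reference breed, and `overall`; attribute `total_contrasts` gives the
#'   number of pairs. Only SNPs that appear in at least one scan's locus
#'   list are included (all scans share the panel locus list).
#' @export
occurrenceTable <- function(results, design = results$design) {
    pairs <- design$pairs
    all_ids <- unique(unlist(lapply(results$posteriors,
                                    function(p) p$snp_id), use.names = FALSE))
    refs <- design$reference_breeds
    counts <- matrix(0L, nrow = length(all_ids), ncol = length(refs),
                     dimnames = list(all_ids, refs))
    for (k in seq_len(nrow(pairs))) {
        hits <- results$significant[[k]]
        if (length(hits))
            counts[hits, pairs$reference[k]] <-
                counts[hits, pairs$reference[k]] + 1L
    }
    out <- data.frame(snp_id = all_ids, counts,
                      overall = as.integer(rowSums(counts)),
                      stringsAsFactors = FALSE, check.names = FALSE,
                      row.names = NULL)
    attr(out, "total_contrasts") <- nrow(pairs)
    out
}

#' Retain SNPs recurrently significant across contrasts
#'
#' Keeps SNPs whose overall occurrence count reaches `min_count`
#' (inclusive, "at least"). The study threshold is 15 of 60 contrasts
#' (25\%); a fractional threshold may be given instead and is resolved
#' against the design's total contrast count, but an absolute `min_count`
#' wins when both are supplied.
#'
#' @param table An occurrence table from [occurrenceTable()].
#' @param min_count Absolute occurrence threshold (>= 1), or `NULL`.
#' @param min_fraction Fractional alternative in (0, 1], resolved as
#'   `ceiling(min_fraction * total_contrasts)`.
#' @param loci Optional \linkS4class{GenotypePanel} or GRanges supplying
#'   chromosome/position for sorting; without it, SNPs keep table order.
#' @return Character vector of retained SNP ids, sorted by chromosome then
#'   position when `loci` is given.
#' @export
applyOccurrenceThreshold <- function(table, min_count = 15L,
                                     min_fraction = NULL, loci = NULL) {
    if (is.null(min_count)) {
        if (is.null(min_fraction))
            stop("one of 'min_count' or 'min_fraction' is required")
        total <- attr(table, "total_contrasts")
        if (is.null(total))
            stop("table lacks a 'total_contrasts' attribute")
        min_count <- ceiling(min_fraction * total)
    }
    stopifnot(min_count >= 1)
    kept <- table$snp_id[table$overall >= min_count]
    if (!is.null(loci) && length(kept)) {
        gr <- if (methods::is(loci, "GenotypePanel"))
            SummarizedExperiment::rowRanges(loci) else loci
        gr <- gr[names(gr) %in% kept]
        chrom <- as.character(GenomeInfoDb::seqnames(gr))
        chrom_key <- suppressWarnings(as.numeric(chrom))
        ord <- order(is.na(chrom_key), chrom_key, chrom,
                     GenomicRanges::start(gr))
        kept <- names(gr)[ord]
    }
    kept
}
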