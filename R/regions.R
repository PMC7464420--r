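#' Flanking window around a SNP
#'
#' Expands SNP positions into windows of `position +/- half_width` base
#' pairs (1-based inclusive), clamped at 1 on the left. The study uses
#' +/- 250 kbp, motivated by the extent of linkage disequilibrium in the
#' cattle genome (useful LD rarely exceeds 500 kbp).
#'
#' @param loci A \linkS4class{GenotypePanel}, a GRanges of SNP positions, or
#'   a data.frame with columns `chrom`, `snp_id`, `position_bp`.
#' @param half_width Flank size in bp (>= 0).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, window ends are clamped to the chromosome end as well.
#' @return A GRanges of windows, one per SNP, named by SNP id, with a
#'   `source_snps` metadata column (CharacterList).
#' @export
snpWindow <- function(loci, half_width = 250000L, chrom_lengths = NULL) {
    stopifnot(half_width >= 0)
    gr <- .as_locus_granges(loci)
    pos <- GenomicRanges::start(gr)
    end <- pos + as.integer(half_width)
    if (!is.null(chrom_lengths)) {
        len <- chrom_lengths[as.character(GenomeInfoDb::seqnames(gr))]
        end <- ifelse(!is.na(len), pmin(end, as.integer(len)), end)
    }
    win <- GenomicRanges::GRanges(
        seqnames = GenomeInfoDb::seqnames(gr),
        ranges = IRanges::IRanges(start = pmax(1L, pos - as.integer(half_width)),
                                  end = end))
    names(win) <- names(gr)
    S4Vectors::mcols(win)$source_snps <- IRanges::CharacterList(
        as.list(names(gr)))
    win
}

.as_locus_granges <- function(loci) {
    if (methods::is(loci, "GenotypePanel"))
        return(SummarizedExperiment::rowRanges(loci))
    if (methods::is(loci, "GRanges"))
        return(loci)
    if (is.data.frame(loci)) {
        gr <- GenomicRanges::GRanges(
            seqnames = as.character(loci$chrom),
            ranges = IRanges::IRanges(start = as.integer(loci$position_bp),
                                      width = 1L))
        names(gr) <- loci$snp_id
        return(gr)
    }
    stop("unsupported locus input of class ", class(loci)[1])
}

#' Merge overlapping or adjacent windows
#'
#' Per chromosome, windows that overlap or are book-ended (adjacent with no
#' gap) are merged into one; their source SNP lists are unioned. The output
#' is sorted and covers exactly the union of input base pairs.
#'
#' @param windows A GRanges as from [snpWindow()].
#' @return A sorted, disjoint GRanges with a `source_snps` metadata column.
#' @export
mergeWindows <- function(windows) {
    if (!length(windows)) return(windows)
    if (is.null(S4Vectors::mcols(windows)$source_snps))
        S4Vectors::mcols(windows)$source_snps <-
            IRanges::CharacterList(as.list(names(windows)))
    sorted <- GenomicRanges::sort(windows, ignore.strand = TRUE)
    merged <- GenomicRanges::reduce(sorted, with.revmap = TRUE,
                                    ignore.strand = TRUE)
    sorted_src <- S4Vectors::mcols(sorted)$source_snps
    revmap <- S4Vectors::mcols(merged)$revmap
    S4Vectors::mcols(merged) <- NULL
    S4Vectors::mcols(merged)$source_snps <- IRanges::CharacterList(
        lapply(revmap, function(ix)
            sort(unique(unlist(sorted_src[ix], use.names = FALSE)))))
    merged
}

#' Interval delimited by a set of SNPs
#'
#' The window spanning from the smallest to the largest SNP position on one
#' chromosome, with no flanks — e.g. the BTA14 interval delimited by the
#' outermost of the nine recurrently significant SNPs there.
#'
#' @param loci As in [snpWindow()]; at least 2 loci, all on one chromosome.
#' @return A length-1 GRanges with `source_snps` listing all delimiting
#'   SNPs.
#' @export
delimitedInterval <- function(loci) {
    gr <- .as_locus_granges(loci)
    if (length(gr) < 2L)
        stop("need at least 2 loci to delimit an interval")
    chrom <- unique(as.character(GenomeInfoDb::seqnames(gr)))
    if (length(chrom) != 1L)
        stop("loci span multiple chromosomes: ",
             paste(chrom, collapse = ", "))
    pos <- GenomicRanges::start(gr)
    out <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = min(pos), end = max(pos)))
    S4Vectors::mcols(out)$source_snps <- IRanges::CharacterList(
        list(sort(names(gr))))
    out
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF3 input (already 1-based inclusive) is restricted to
#' rows of type `gene`, with the symbol taken from the `Name` attribute
#' (falling back to `gene`, then `ID`). Strand is ignored downstream.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; guessed from the file extension when
#'   missing.
#' @return A GRanges of genes with a `symbol` metadata column.
#' @export
readGeneAnnotation <- function(path, format = c("auto", "bed", "gff3")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
            "bed"
        else if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE))
            "gff3"
        else stop("cannot guess annotation format from '", path,
                  "'; pass format=")
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = if (format == "bed") "BED"
                                          else "GFF3"),
        error = function(e) stop("failed to parse ", format, " file '",
                                 path, "': ", conditionMessage(e)))
    if (format == "gff3") {
        gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
        sym <- as.character(gr$Name)
        if (!is.null(gr$gene)) sym[is.na(sym)] <- as.character(gr$gene)[is.na(sym)]
        if (!is.null(gr$ID)) sym[is.na(sym)] <- as.character(gr$ID)[is.na(sym)]
    } else {
        sym <- as.character(gr$name)
    }
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$symbol <- sym
    GenomicRanges::strand(out) <- "*"
    out
}

#' Genes overlapping each region
#'
#' A gene is reported for a region when the two intervals share at least
#' one base (1-based inclusive coordinates); genes are listed in order of
#' their start position.
#'
#' @param regions A GRanges of windows/regions.
#' @param genes A GRanges of genes with a `symbol` metadata column, as from
#'   [readGeneAnnotation()].
#' @return `regions` with an added `genes` metadata column (CharacterList
#'   of overlapping gene symbols, ordered by gene start).
#' @export
genesInRegions <- function(regions, genes) {
    genes <- genes[order(as.character(GenomeInfoDb::seqnames(genes)),
                         GenomicRanges::start(genes))]
    hits <- GenomicRanges::findOverlaps(regions, genes, ignore.strand = TRUE)
    sym_by_region <- split(S4Vectors::mcols(genes)$symbol[
        S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_along(regions)))
    gene_lists <- IRanges::CharacterList(lapply(sym_by_region, unname))
    names(gene_lists) <- names(regions)
    S4Vectors::mcols(regions)$genes <- gene_lists
    regions
}

#' Assemble the per-SNP selection-signature report
#'
#' One row per retained SNP: chromosome, SNP id, per-reference-breed counts
#' of significant contrasts, the overall count, the SNP position, its
#' considered interval ("start-end"), and the comma-separated overlapping
#' genes — the layout of the study's candidate-SNP table. Rows are sorted
#' by chromosome, then position.
#'
#' @param occurrences Occurrence table ([occurrenceTable()]), restricted or
#'   not; only SNPs in `regions_annotated` are reported.
#' @param regions_annotated Annotated per-SNP windows: a GRanges named by
#'   SNP id with `genes` metadata (see [snpWindow()] + [genesInRegions()]).
#' @param loci Locus positions, as in [snpWindow()].
#' @param design The `contrast_design` (fixes the reference-breed column
#'   order).
#' @param path Optional output path; when given the TSV is written there.
#' @return The report as a data.frame (invisibly when `path` is given).
#' @export
reportTable <- function(occurrences, regions_annotated, loci, design,
                        path = NULL) {
    gr <- .as_locus_granges(loci)
    ids <- names(regions_annotated)
    refs <- design$reference_breeds
    if (length(ids)) {
        pos <- GenomicRanges::start(gr)[match(ids, names(gr))]
        chrom <- as.character(GenomeInfoDb::seqnames(gr))[match(ids, names(gr))]
        occ <- occurrences[match(ids, occurrences$snp_id), , drop = FALSE]
        genes <- vapply(S4Vectors::mcols(regions_annotated)$genes,
                        paste, character(1), collapse = ", ")
        out <- data.frame(CHR = chrom, `SNP ID` = ids,
                          check.names = FALSE, stringsAsFactors = FALSE)
        for (r in refs) out[[toupper(r)]] <- occ[[r]]
        out$OVERALL <- occ$overall
        out$POSITION <- pos
        out$`CONSIDERED INTERVAL` <- paste0(
            GenomicRanges::start(regions_annotated), "-",
            GenomicRanges::end(regions_annotated))
        out$GENES <- genes
        chrom_key <- suppressWarnings(as.numeric(out$CHR))
        out <- out[order(is.na(chrom_key), chrom_key, out$CHR, out$POSITION),
                   , drop = FALSE]
        rownames(out) <- NULL
    } else {
        out <- data.frame(CHR = character(), `SNP ID` = character(),
                          check.names = FALSE, stringsAsFactors = FALSE)
        for (r in refs) out[[toupper(r)]] <- integer()
        out$OVERALL <- integer()
        out$POSITION <- integer()
        out$`CONSIDERED INTERVAL` <- character()
        out$GENES <- character()
    }
    if (!is.null(path)) {
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(out))
    }
    out
}
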