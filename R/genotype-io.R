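#' Read a PED/MAP genotype panel
#'
#' Reads whitespace-delimited PLINK text PED/MAP files into a
#' \linkS4class{GenotypePanel}. The MAP file has four columns (chromosome,
#' SNP id, genetic position, physical bp position); the PED file has six
#' leading columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele characters per locus, with `"0"` marking a missing
#' allele. The breed label is taken from the PED family-id column, the
#' standard convention for multi-breed panels.
#'
#' The per-locus A allele is the first non-missing allele character
#' encountered in file order; a genotype with either allele missing is
#' recorded as `NA`. Gzip-compressed files are read transparently.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A \linkS4class{GenotypePanel}.
#' @seealso [writePedMap()], [alleleCounts()]
#' @export
readPedMap <- function(ped_path, map_path) {
    map <- read.table(map_path, header = FALSE, colClasses = "character",
                      col.names = c("chrom", "snp_id", "cm", "bp"))
    n_loci <- nrow(map)
    if (anyDuplicated(map$snp_id))
        stop("duplicated SNP ids in MAP file: ",
             paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))

    lines <- readLines(ped_path)
    lines <- lines[nzchar(trimws(lines))]
    n_ind <- length(lines)
    calls <- matrix(NA_integer_, nrow = n_loci, ncol = n_ind)
    alleleA <- rep(NA_character_, n_loci)
    alleleB <- rep(NA_character_, n_loci)

    toks <- strsplit(trimws(lines), "[ \t]+")
    n_tok <- lengths(toks)
    if (any(n_tok != 6L + 2L * n_loci))
        stop(sprintf(
            "PED line %d has %d genotype fields; MAP declares %d loci",
            which(n_tok != 6L + 2L * n_loci)[1L],
            max(0L, n_tok[n_tok != 6L + 2L * n_loci][1L] - 6L), n_loci))
    tok_mat <- matrix(unlist(toks, use.names = FALSE),
                      nrow = n_ind, byrow = TRUE)
    breed <- tok_mat[, 1L]
    iid <- tok_mat[, 2L]
    for (i in seq_len(n_loci)) {
        al1 <- tok_mat[, 5L + 2L * i]
        al2 <- tok_mat[, 6L + 2L * i]
        seen <- setdiff(unique(as.vector(rbind(al1, al2))), "0")
        if (length(seen) > 2L)
            stop(sprintf("locus '%s' has more than two alleles (%s)",
                         map$snp_id[i], paste(seen, collapse = ",")))
        alleleA[i] <- if (length(seen) >= 1L) seen[1L] else NA_character_
        alleleB[i] <- if (length(seen) == 2L) seen[2L] else NA_character_
        ok <- al1 != "0" & al2 != "0"
        calls[i, ok] <- (al1[ok] == alleleA[i]) + (al2[ok] == alleleA[i])
    }
    rownames(calls) <- map$snp_id
    GenotypePanel(calls = calls, chrom = map$chrom,
                  position_bp = as.integer(map$bp),
                  breed = breed, indiv_id = iid,
                  alleleA = alleleA, alleleB = alleleB)
}

#' Write a genotype panel as PED/MAP
#'
#' Inverse of [readPedMap()]: a round trip reproduces the call matrix, map
#' and breed labels exactly for any panel in first-seen-A orientation —
#' i.e. whose per-locus A allele occurs in the locus's first non-missing
#' genotype, which holds for every panel produced by [readPedMap()].
#' Heterozygotes are written A-allele first to preserve that orientation.
#' For a panel violating it (possible only when constructed by hand), the
#' file read back differs by a per-locus A/B relabeling (`calls` becomes
#' `2 - calls` there), which the F-model likelihood is invariant to; a
#' second round trip is then an exact fixed point. Missing genotypes are
#' written as `"0 0"`; loci whose B (or A) allele was never observed use a
#' placeholder character for the unobserved allele.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param ped_path,map_path Output paths. A `.gz` suffix compresses.
#' @return Invisibly, `NULL`.
#' @export
writePedMap <- function(panel, ped_path, map_path) {
    rr <- SummarizedExperiment::rowRanges(panel)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    map <- data.frame(chrom = chrom,
                      snp_id = if (nrow(panel)) rownames(panel)
                               else character(0),
                      cm = rep(0L, length(chrom)),
                      bp = GenomicRanges::start(rr))
    con <- .open_write(map_path)
    write.table(map, con, quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    close(con)

    calls <- genotypeCalls(panel)
    al <- alleleLabels(panel)
    aA <- ifelse(is.na(al[, "A"]), "A", al[, "A"])
    aB <- ifelse(is.na(al[, "B"]), ifelse(aA == "B", "C", "B"), al[, "B"])
    cd <- SummarizedExperiment::colData(panel)
    con <- .open_write(ped_path)
    on.exit(close(con))
    for (k in seq_len(ncol(panel))) {
        g <- calls[, k]
        a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, aA, aB))
        a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, aA, aB))
        writeLines(paste(c(cd$breed[k], cd$indiv_id[k], "0", "0", "0", "-9",
                           as.vector(rbind(a1, a2))), collapse = " "), con)
    }
    invisible(NULL)
}

.open_write <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Read/write allele-count tables as text
#'
#' Plain whitespace-delimited exchange format for pairwise scans: one row
#' per locus with columns `snp_id`, then `a`, `n` for each population
#' (`a_P1 n_P1 a_P2 n_P2 ...`), with a header line naming the populations.
#'
#' @param counts An \linkS4class{AlleleCounts}.
#' @param path File path (`.gz` compresses on write).
#' @return `readAlleleCounts()` returns an \linkS4class{AlleleCounts}
#'   (positions are not stored in this format and default to the row
#'   index); `writeAlleleCounts()` returns `NULL` invisibly.
#' @export
writeAlleleCounts <- function(counts, path) {
    a <- countsA(counts); n <- countsTotal(counts)
    out <- data.frame(snp_id = rownames(a), check.names = FALSE)
    for (j in seq_len(ncol(a))) {
        out[[paste0("a_", colnames(a)[j])]] <- a[, j]
        out[[paste0("n_", colnames(a)[j])]] <- n[, j]
    }
    con <- .open_write(path)
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname writeAlleleCounts
#' @export
readAlleleCounts <- function(path) {
    d <- read.table(path, header = TRUE, check.names = FALSE)
    acols <- grep("^a_", colnames(d), value = TRUE)
    pops <- sub("^a_", "", acols)
    a <- as.matrix(d[, paste0("a_", pops), drop = FALSE])
    n <- as.matrix(d[, paste0("n_", pops), drop = FALSE])
    dimnames(a) <- dimnames(n) <- list(d$snp_id, pops)
    rr <- GenomicRanges::GRanges("un",
                                 IRanges::IRanges(seq_len(nrow(d)),
                                                  width = 1L))
    names(rr) <- d$snp_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(a = a, n = n), rowRanges = rr)
    methods::new("AlleleCounts", se)
}

#' Per-population allele counts
#'
#' Collapses a genotype panel to the sufficient statistics of the F-model
#' likelihood: for each locus i and requested population j, the A-allele
#' count \eqn{a_{ij}} (sum of dosages over non-missing individuals) and the
#' total called alleles \eqn{n_{ij} = 2 \times} (non-missing count).
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param populations Character vector of breed labels to tabulate, in the
#'   desired column order.
#' @return An \linkS4class{AlleleCounts} with one column per population.
#' @export
alleleCounts <- function(panel, populations) {
    have <- unique(breeds(panel))
    missing_pop <- setdiff(populations, have)
    if (length(missing_pop))
        stop("breed label(s) not in panel: ",
             paste(missing_pop, collapse = ", "))
    calls <- genotypeCalls(panel)
    a <- matrix(0L, nrow = nrow(panel), ncol = length(populations),
                dimnames = list(rownames(panel), populations))
    n <- a
    for (j in seq_along(populations)) {
        sub <- calls[, breeds(panel) == populations[j], drop = FALSE]
        a[, j] <- as.integer(rowSums(sub, na.rm = TRUE))
        n[, j] <- as.integer(2L * rowSums(!is.na(sub)))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(a = a, n = n),
        rowRanges = SummarizedExperiment::rowRanges(panel))
    methods::new("AlleleCounts", se)
}
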