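test_that("SNP windows are position +/- half-width, clamped at 1", {
    loci <- data.frame(chrom = c("2", "5"), snp_id = c("sA", "sB"),
                       position_bp = c(6760630L, 100000L))
    w <- snpWindow(loci, 250000L)
    expect_identical(GenomicRanges::start(w), c(6510630L, 1L))
    expect_identical(GenomicRanges::end(w), c(7010630L, 350000L))
    expect_identical(names(w), c("sA", "sB"))
    # degenerate half-width gives a single-base window
    w0 <- snpWindow(loci, 0L)
    expect_identical(GenomicRanges::width(w0), c(1L, 1L))
    # monotone in half_width: wider flank contains narrower
    w2 <- snpWindow(loci, 400000L)
    expect_true(all(IRanges::overlapsAny(w, w2)))
    expect_true(all(GenomicRanges::start(w2) <= GenomicRanges::start(w) &
                    GenomicRanges::end(w2) >= GenomicRanges::end(w)))
})

test_that("windows clamp to chromosome lengths when provided", {
    loci <- data.frame(chrom = c("1", "2"), snp_id = c("x", "y"),
                       position_bp = c(900L, 900L))
    w <- snpWindow(loci, 200L, chrom_lengths = c("1" = 1000L))
    expect_identical(GenomicRanges::end(w), c(1000L, 1100L))
})

test_that("window merging unions overlapping and book-ended windows", {
    loci <- data.frame(chrom = c("14", "14"),
                       snp_id = c("BTB-01532239", "BTB-01530788"),
                       position_bp = c(22781305L, 22867321L))
    merged <- mergeWindows(snpWindow(loci, 250000L))
    expect_identical(length(merged), 1L)
    expect_identical(GenomicRanges::start(merged), 22531305L)
    expect_identical(GenomicRanges::end(merged), 23117321L)
    expect_identical(S4Vectors::mcols(merged)$source_snps[[1]],
                     sort(c("BTB-01532239", "BTB-01530788")))

    # different chromosomes never merge
    loci2 <- data.frame(chrom = c("1", "2"), snp_id = c("x", "y"),
                        position_bp = c(1000L, 1000L))
    expect_identical(length(mergeWindows(snpWindow(loci2, 500L))), 2L)

    # book-ended (adjacent, gap 0) windows merge
    adj <- GenomicRanges::GRanges(c("3", "3"),
                                  IRanges::IRanges(c(1, 11), c(10, 20)))
    names(adj) <- c("a", "b")
    expect_identical(length(mergeWindows(adj)), 1L)
})

test_that("merged windows cover exactly the union of base pairs", {
    set.seed(14)
    for (rep in 1:10) {
        n <- sample(1:8, 1)
        start <- sample(1:200, n, replace = TRUE)
        width <- sample(1:60, n, replace = TRUE)
        gr <- GenomicRanges::GRanges("7", IRanges::IRanges(start,
                                                           start + width))
        names(gr) <- paste0("w", seq_len(n))
        merged <- mergeWindows(gr)
        # bitmap oracle on small coordinates
        bitmap <- rep(FALSE, 400)
        for (k in seq_len(n))
            bitmap[start[k]:(start[k] + width[k])] <- TRUE
        covered <- rep(FALSE, 400)
        for (k in seq_along(merged))
            covered[GenomicRanges::start(merged)[k]:
                    GenomicRanges::end(merged)[k]] <- TRUE
        expect_identical(covered, bitmap)
        # disjoint and sorted
        if (length(merged) > 1) {
            expect_true(all(diff(GenomicRanges::start(merged)) > 0))
            expect_true(all(GenomicRanges::start(merged)[-1] >
                            GenomicRanges::end(merged)[-length(merged)] + 1))
        }
    }
})

test_that("the delimited interval spans min to max position without flanks", {
    loci <- data.frame(chrom = rep("14", 3),
                       snp_id = c("s1", "s2", "s3"),
                       position_bp = c(25472332L, 22781305L, 23630896L))
    iv <- delimitedInterval(loci)
    expect_identical(GenomicRanges::start(iv), 22781305L)
    expect_identical(GenomicRanges::end(iv), 25472332L)
    # order invariance
    iv2 <- delimitedInterval(loci[c(3, 1, 2), ])
    expect_equal(GenomicRanges::ranges(iv), GenomicRanges::ranges(iv2))
    # identical positions give a zero-width (single-base) window
    same <- data.frame(chrom = c("1", "1"), snp_id = c("a", "b"),
                       position_bp = c(5L, 5L))
    expect_identical(GenomicRanges::width(delimitedInterval(same)), 1L)
    mixed <- data.frame(chrom = c("1", "2"), snp_id = c("a", "b"),
                        position_bp = c(1L, 2L))
    expect_error(delimitedInterval(mixed), "chromosome")
    expect_error(delimitedInterval(loci[1, , drop = FALSE]), "at least 2")
})

test_that("BED input converts to 1-based inclusive; GFF3 keeps gene rows", {
    dir <- withr::local_tempdir()
    bed <- file.path(dir, "genes.bed")
    writeLines("14\t23300000\t23400000\tSDR16C5", bed)
    g <- readGeneAnnotation(bed)
    expect_identical(GenomicRanges::start(g), 23300001L)
    expect_identical(GenomicRanges::end(g), 23400000L)
    expect_identical(g$symbol, "SDR16C5")

    gff <- file.path(dir, "genes.gff3")
    writeLines(c("##gff-version 3",
                 "14\ttest\tgene\t22700000\t22800000\t.\t+\t.\tID=gene1;Name=XKR4",
                 "14\ttest\tmRNA\t22700000\t22750000\t.\t+\t.\tID=rna1",
                 "14\ttest\texon\t22700000\t22710000\t.\t+\t.\tParent=rna1"),
               gff)
    g2 <- readGeneAnnotation(gff)
    expect_identical(length(g2), 1L)
    expect_identical(GenomicRanges::start(g2), 22700000L)  # unchanged
    expect_identical(GenomicRanges::end(g2), 22800000L)
    expect_identical(g2$symbol, "XKR4")

    expect_error(readGeneAnnotation(file.path(dir, "x.unknown")), "format")
})

test_that("gene overlap requires >= 1 shared base and orders by start", {
    region <- GenomicRanges::GRanges("14", IRanges::IRanges(100, 200))
    names(region) <- "win1"
    genes <- GenomicRanges::GRanges(
        c("14", "14", "14", "14", "14"),
        IRanges::IRanges(c(150, 90, 200, 201, 1), c(160, 105, 300, 350, 99)))
    S4Vectors::mcols(genes)$symbol <- c("inside", "straddle_left",
                                        "straddle_right", "past_end",
                                        "before_start")
    ann <- genesInRegions(region, genes)
    # one shared base suffices (straddle_right shares base 200); adjacency
    # without a shared base (past_end at 201, before_start ending at 99)
    # does not count
    expect_identical(S4Vectors::mcols(ann)$genes[[1]],
                     c("straddle_left", "inside", "straddle_right"))

    # empty annotation gives empty gene lists
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty)$symbol <- character(0)
    ann0 <- genesInRegions(region, empty)
    expect_identical(lengths(S4Vectors::mcols(ann0)$genes), c(win1 = 0L))
})

test_that("gene overlap equals the all-pairs brute force on random fixtures", {
    set.seed(99)
    for (rep in 1:5) {
        nr <- sample(2:5, 1); ng <- sample(3:10, 1)
        rs <- sample(1:500, nr); gs <- sample(1:500, ng)
        regions <- GenomicRanges::GRanges(
            sample(c("1", "2"), nr, TRUE),
            IRanges::IRanges(rs, rs + sample(10:80, nr, TRUE)))
        names(regions) <- paste0("r", seq_len(nr))
        genes <- GenomicRanges::GRanges(
            sample(c("1", "2"), ng, TRUE),
            IRanges::IRanges(gs, gs + sample(5:50, ng, TRUE)))
        S4Vectors::mcols(genes)$symbol <- paste0("g", seq_len(ng))
        ann <- genesInRegions(regions, genes)
        for (k in seq_len(nr)) {
            hits <- character(0)
            for (m in seq_len(ng)) {
                same <- as.character(GenomicRanges::seqnames(regions)[k]) ==
                    as.character(GenomicRanges::seqnames(genes)[m])
                ov <- GenomicRanges::start(genes)[m] <=
                    GenomicRanges::end(regions)[k] &&
                    GenomicRanges::end(genes)[m] >=
                    GenomicRanges::start(regions)[k]
                if (same && ov) hits <- c(hits, paste0("g", m))
            }
            expect_setequal(S4Vectors::mcols(ann)$genes[[k]], hits)
        }
    }
})

test_that("the report table reproduces the published layout and round-trips", {
    design <- buildContrasts(c("G1",  "G2"), c("Angus", "Holstein"))
    occ <- data.frame(snp_id = c("sA", "sB"), Angus = c(1L, 2L),
                      Holstein = c(0L, 2L), overall = c(1L, 4L))
    loci <- data.frame(chrom = c("14", "2"), snp_id = c("sA", "sB"),
                       position_bp = c(22986080L, 6760630L))
    win <- snpWindow(loci, 250000L)
    genes <- GenomicRanges::GRanges("14",
                                    IRanges::IRanges(22990000, 23000000))
    S4Vectors::mcols(genes)$symbol <- "LYN"
    ann <- genesInRegions(win, genes)
    path <- file.path(withr::local_tempdir(), "report.tsv")
    tab <- reportTable(occ, ann, loci, design, path = path)
    expect_identical(colnames(tab),
                     c("CHR", "SNP ID", "ANGUS", "HOLSTEIN", "OVERALL",
                       "POSITION", "CONSIDERED INTERVAL", "GENES"))
    # sorted by chromosome then position: chr2 before chr14
    expect_identical(tab$CHR, c("2", "14"))
    expect_identical(tab$`CONSIDERED INTERVAL`[2], "22736080-23236080")
    expect_identical(tab$GENES[2], "LYN")
    back <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
    expect_identical(as.integer(back$OVERALL), c(4L, 1L))  # chr2 row first
    # empty input gives a header-only file
    e <- reportTable(occ[0, ], ann[0], loci, design,
                     path = file.path(dirname(path), "empty.tsv"))
    expect_identical(nrow(e), 0L)
    expect_identical(length(readLines(file.path(dirname(path),
                                                "empty.tsv"))), 1L)
})
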