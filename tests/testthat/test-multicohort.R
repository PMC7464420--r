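test_that("contrast design is the full product in test-major order", {
    d <- buildContrasts(c("G1", "G2", "G3"), c("R1", "R2"))
    expect_identical(nrow(d$pairs), 6L)
    expect_identical(d$pairs$grey, rep(c("G1", "G2", "G3"), each = 2))
    expect_identical(as.integer(table(d$pairs$grey)), rep(2L, 3))
    expect_identical(nrow(buildContrasts("G", "R")$pairs), 1L)
    expect_error(buildContrasts(c("G", "X"), c("R", "X")), "X")
    expect_error(buildContrasts(character(0), "R"), "non-empty")
})

test_that("the packaged study design yields 60 pairs and 514 animals", {
    fx <- design_fixture()
    d <- buildContrasts(fx$breed[fx$group == "grey"],
                        fx$breed[fx$group == "reference"])
    expect_identical(nrow(d$pairs), 60L)
    expect_identical(sum(fx$n), 514L)
})

test_that("occurrence counts aggregate per reference breed and conserve", {
    design <- buildContrasts(c("G1", "G2"), c("R1", "R2"))
    # hand-built per-pair significance: order G1R1, G1R2, G2R1, G2R2
    results <- list(
        significant = list(c("s1", "s2"), c("s1"), c("s1", "s3"), character(0)),
        posteriors = list(data.frame(snp_id = c("s1", "s2", "s3"))),
        design = design)
    names(results$significant) <- paste(design$pairs$grey,
                                        design$pairs$reference, sep = "|")
    occ <- occurrenceTable(results, design)
    expect_identical(occ$snp_id, c("s1", "s2", "s3"))
    expect_identical(occ$R1, c(2L, 1L, 1L))
    expect_identical(occ$R2, c(1L, 0L, 0L))
    expect_identical(occ$overall, unname(occ$R1 + occ$R2))
    expect_identical(attr(occ, "total_contrasts"), 4L)
    # a SNP significant nowhere keeps an all-zero row
    expect_identical(occ$overall[occ$snp_id == "s3"] -
                     occ$R1[occ$snp_id == "s3"], 0L)
    # permutation of pair order leaves counts unchanged
    perm <- c(3, 1, 4, 2)
    results2 <- results
    results2$significant <- results$significant[perm]
    design2 <- design
    design2$pairs <- design$pairs[perm, ]
    occ2 <- occurrenceTable(results2, design2)
    expect_identical(occ$overall, occ2$overall[match(occ$snp_id, occ2$snp_id)])
})

test_that("occurrence thresholding is inclusive and monotone", {
    occ <- data.frame(snp_id = c("a", "b", "c"),
                      overall = c(15L, 14L, 60L))
    attr(occ, "total_contrasts") <- 60L
    expect_setequal(applyOccurrenceThreshold(occ, 15L), c("a", "c"))
    expect_identical(applyOccurrenceThreshold(occ, 16L), "c")
    # fractional alternative resolves against the design size
    expect_setequal(applyOccurrenceThreshold(occ, min_count = NULL,
                                             min_fraction = 0.25),
                    c("a", "c"))
    # absolute count wins when both are given
    expect_identical(applyOccurrenceThreshold(occ, 16L, min_fraction = 0.01),
                     "c")
    # raising the threshold never adds SNPs
    for (k in 1:60) {
        lo <- applyOccurrenceThreshold(occ, k)
        hi <- applyOccurrenceThreshold(occ, k + 1L)
        expect_true(all(hi %in% lo))
    }
    expect_identical(applyOccurrenceThreshold(occ[0, ], 15L), character(0))
})

test_that("retained SNPs sort by chromosome then position when loci given", {
    occ <- data.frame(snp_id = c("s1", "s2", "s3"), overall = c(20L, 20L, 20L))
    gr <- GenomicRanges::GRanges(c("14", "2", "14"),
                                 IRanges::IRanges(c(500, 100, 100), width = 1))
    names(gr) <- c("s1", "s2", "s3")
    expect_identical(applyOccurrenceThreshold(occ, 1L, loci = gr),
                     c("s2", "s3", "s1"))
})

test_that("convergently selected loci accumulate occurrences, neutral do not", {
    sim <- simulatePanel(syntheticConfig(n_grey = 3, n_reference = 2,
                                         n_per_breed = 24, n_loci = 150,
                                         frac_selected = 0.04, seed = 31))
    design <- buildContrasts(sprintf("GREY%02d", 1:3),
                             sprintf("REF%02d", 1:2))
    res <- runAllContrasts(sim$panel, design, quick_mcmc(seed = 17))
    occ <- occurrenceTable(res, design)
    sel <- sim$truth$selected[match(occ$snp_id, sim$truth$snp_id)]
    # the convergent signal concentrates on truly selected loci
    expect_gt(mean(occ$overall[sel]), mean(occ$overall[!sel]))
    expect_gte(max(occ$overall[sel]), 2L)
    # neutral loci essentially never recur across contrasts
    expect_lte(max(occ$overall[!sel]), 1L)
})

test_that("runAllContrasts subsets breeds, caches, and aborts on bad design", {
    set.seed(11)
    sim <- simulatePanel(syntheticConfig(n_grey = 2, n_reference = 1,
                                         n_loci = 40, n_per_breed = 12,
                                         frac_selected = 0, seed = 3))
    design <- buildContrasts(c("GREY01", "GREY02"), "REF01")
    ctl <- quick_mcmc(seed = 6)
    cache <- withr::local_tempdir()
    r1 <- runAllContrasts(sim$panel, design, ctl, cache_dir = cache)
    expect_named(r1$significant, c("GREY01|REF01", "GREY02|REF01"))
    expect_identical(length(r1$posteriors), 2L)
    n_cached <- length(list.files(cache))
    expect_identical(n_cached, 2L)
    # cached rerun reproduces results exactly
    r2 <- runAllContrasts(sim$panel, design, ctl, cache_dir = cache)
    expect_identical(r1$significant, r2$significant)
    expect_identical(r1$posteriors, r2$posteriors)

    bad <- buildContrasts(c("GREY01", "NOPE"), "REF01")
    expect_error(runAllContrasts(sim$panel, bad, ctl), "NOPE")

    empty <- buildContrasts("GREY01", "REF01")
    empty$pairs <- empty$pairs[0, ]
    r0 <- runAllContrasts(sim$panel, empty, ctl)
    expect_identical(length(r0$significant), 0L)
})
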