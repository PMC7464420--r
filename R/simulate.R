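#' Balding-Nichols subpopulation allele frequency
#'
#' Draws a subpopulation frequency around ancestral frequency `p` with
#' differentiation `fst`:
#' \deqn{\tilde p \sim \mathrm{Beta}\!\left(p\,\frac{1-F_{ST}}{F_{ST}},\;
#'   (1-p)\,\frac{1-F_{ST}}{F_{ST}}\right)}
#' so that \eqn{E[\tilde p] = p} and
#' \eqn{\mathrm{Var}[\tilde p] = F_{ST}\, p (1-p)} — the frequency model
#' underlying the F-model prior structure.
#'
#' @param p Ancestral frequency(ies), strictly in (0, 1).
#' @param fst Differentiation level(s), strictly in (0, 1).
#' @param n Number of draws (recycling `p` and `fst`).
#' @return Numeric vector of frequencies in (0, 1).
#' @export
baldingNicholsFreq <- function(p, fst, n = max(length(p), length(fst))) {
    if (any(p <= 0 | p >= 1) || any(fst <= 0 | fst >= 1))
        stop("domain error: p and fst must be strictly inside (0, 1)")
    theta <- (1 - fst) / fst
    rbeta(n, p * theta, (1 - p) * theta)
}

#' Synthetic multi-breed panel settings
#'
#' Defaults emulate the grey-cattle study design at desk scale: 15 test
#' ("grey") breeds and 4 reference breeds of 24 individuals each, 1000
#' biallelic autosomal loci (a downsampled medium-density array), 2\% of
#' loci convergently differentiated in all grey breeds with locus effect
#' 2.5 on the logit-FST scale, population effects drawn from
#' Normal(-2, 0.3^2) (baseline FST near 0.12), ancestral frequencies
#' uniform on (0.05, 0.95), and 2\% missing calls.
#'
#' @param n_grey,n_reference Breed counts.
#' @param n_per_breed Individuals per breed.
#' @param n_loci Number of loci.
#' @param frac_selected Fraction of loci under convergent selection.
#' @param alpha_selected Locus effect at selected loci (logit scale).
#' @param beta_mean,beta_sd Population-effect distribution.
#' @param ancestral_freq_range Range of the uniform ancestral frequency.
#' @param missing_rate i.i.d. missing-call probability.
#' @param n_chrom Number of chromosome labels loci are spread over.
#' @param seed Master seed.
#' @return A list of class `synthetic_config`.
#' @export
syntheticConfig <- function(n_grey = 15L, n_reference = 4L,
                            n_per_breed = 24L, n_loci = 1000L,
                            frac_selected = 0.02, alpha_selected = 2.5,
                            beta_mean = -2.0, beta_sd = 0.3,
                            ancestral_freq_range = c(0.05, 0.95),
                            missing_rate = 0.02, n_chrom = 10L, seed = 1L) {
    stopifnot(n_grey >= 1, n_reference >= 1, n_per_breed >= 1, n_loci >= 0,
              frac_selected >= 0, frac_selected <= 1,
              missing_rate >= 0, missing_rate < 1,
              length(ancestral_freq_range) == 2,
              ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
              ancestral_freq_range[1] <= ancestral_freq_range[2])
    structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a multi-breed genotype panel with convergent selection
#'
#' Generates a \linkS4class{GenotypePanel} with the structure the
#' multi-cohort scan assumes. Per locus i, an ancestral frequency
#' `p_i ~ U(range)`; per breed j, a population effect
#' `beta_j ~ N(beta_mean, beta_sd^2)` giving a breed differentiation level
#' `fst_j = plogis(beta_j)`. Neutral loci draw each breed's frequency from
#' the Balding-Nichols distribution around `p_i` at `fst_j`. At selected
#' loci, every grey breed instead draws around a shared derived frequency
#' `p_i' = clamp(p_i + 0.5, 0.05, 0.95)` with elevated differentiation
#' `fst = plogis(alpha_selected + beta_j)` — the same locus shifted the
#' same way in all grey breeds, reproducing a convergent signal against
#' every reference breed rather than independent breed-specific noise.
#' Genotypes are Binomial(2, freq) under Hardy-Weinberg equilibrium;
#' missing calls are dropped i.i.d.
#'
#' Grey breeds are labelled `GREY01..`, references `REF01..`; loci are
#' spread uniformly over `n_chrom` chromosomes at 50 kbp spacing.
#'
#' @param config A [syntheticConfig()] list.
#' @return A list: `panel` (\linkS4class{GenotypePanel}) and `truth`
#'   (data.frame with `snp_id`, `selected` flag, realized `alpha`,
#'   ancestral `p`, derived `p_prime`; attribute `beta` holds the per-breed
#'   effects).
#' @export
simulatePanel <- function(config = syntheticConfig()) {
    cfg <- config
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(cfg$seed)

    grey <- sprintf("GREY%02d", seq_len(cfg$n_grey))
    refs <- sprintf("REF%02d", seq_len(cfg$n_reference))
    breed <- rep(c(grey, refs), each = cfg$n_per_breed)
    n_ind <- length(breed)
    n_loci <- cfg$n_loci

    beta <- rnorm(cfg$n_grey + cfg$n_reference, cfg$beta_mean, cfg$beta_sd)
    names(beta) <- c(grey, refs)
    p <- runif(n_loci, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
    n_sel <- round(cfg$frac_selected * n_loci)
    selected <- rep(FALSE, n_loci)
    if (n_sel > 0) selected[sample.int(n_loci, n_sel)] <- TRUE
    p_prime <- pmin(pmax(p + 0.5, 0.05), 0.95)

    calls <- matrix(NA_integer_, nrow = n_loci, ncol = n_ind)
    for (b in c(grey, refs)) {
        cols <- which(breed == b)
        is_grey <- b %in% grey
        fst_neut <- stats::plogis(beta[b])
        centre <- p
        fst <- rep(fst_neut, n_loci)
        if (is_grey && any(selected)) {
            centre[selected] <- p_prime[selected]
            fst[selected] <- stats::plogis(cfg$alpha_selected + beta[b])
        }
        freq <- baldingNicholsFreq(centre, fst, n = n_loci)
        for (k in cols)
            calls[, k] <- rbinom(n_loci, 2L, freq)
    }
    if (cfg$missing_rate > 0 && length(calls))
        calls[runif(length(calls)) < cfg$missing_rate] <- NA_integer_

    snp_id <- sprintf("snp%05d", seq_len(n_loci))
    rownames(calls) <- snp_id
    chrom <- as.character(rep_len(seq_len(cfg$n_chrom), n_loci))
    pos <- integer(n_loci)
    for (ch in unique(chrom)) {
        ix <- which(chrom == ch)
        pos[ix] <- 50000L * seq_along(ix)
    }
    panel <- GenotypePanel(calls = calls, chrom = chrom, position_bp = pos,
                           breed = breed,
                           indiv_id = sprintf("id%04d", seq_len(n_ind)),
                           alleleA = "A", alleleB = "G")
    truth <- data.frame(snp_id = snp_id, selected = selected,
                        alpha = ifelse(selected, cfg$alpha_selected, 0),
                        p = p, p_prime = p_prime,
                        stringsAsFactors = FALSE)
    attr(truth, "beta") <- beta
    list(panel = panel, truth = truth)
}

#' Hudson estimator of pairwise FST
#'
#' Ratio-of-averages Hudson estimator across loci for two populations,
#' computed from an \linkS4class{AlleleCounts} table with two columns.
#' Used to check that simulated panels realise the differentiation level
#' their population effects imply.
#'
#' @param counts An \linkS4class{AlleleCounts} with exactly 2 populations.
#' @return A single FST estimate.
#' @export
hudsonFst <- function(counts) {
    stopifnot(ncol(counts) == 2L)
    a <- countsA(counts)
    n <- countsTotal(counts)
    ok <- n[, 1] > 1 & n[, 2] > 1
    p1 <- a[ok, 1] / n[ok, 1]
    p2 <- a[ok, 2] / n[ok, 2]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n[ok, 1] - 1) -
        p2 * (1 - p2) / (n[ok, 2] - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
}
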