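#' MCMC settings for the F-model outlier scan
#'
#' Defaults mirror the standard settings of the reference Bayesian
#' FST-outlier tool: 20 pilot runs of 5000 iterations that adapt the
#' proposal distributions, a burn-in of 50,000 iterations, and 5000 retained
#' samples at a thinning interval of 10. `prior_odds` is the prior odds for
#' the neutral model, P(alpha excluded)/P(alpha included); 10 encodes the
#' expectation that roughly one locus in eleven departs from neutrality a
#' priori. Test-scale analyses shorten the chains via these arguments.
#'
#' @param n_pilot Number of pilot runs used to tune proposals.
#' @param pilot_length Iterations per pilot run.
#' @param burn_in Burn-in iterations after the pilots.
#' @param n_samples Number of retained posterior samples.
#' @param thinning Iterations between retained samples.
#' @param prior_odds Prior odds of the neutral model (> 0).
#' @param alpha_prior_sd Standard deviation of the Gaussian prior on the
#'   locus effect alpha.
#' @param beta_prior_mean,beta_prior_sd Gaussian prior on the population
#'   effect beta (logit scale; the default mean -1 centres Fst near 0.27).
#' @param seed Master seed; every stream of the sampler derives from it.
#' @return A list of class `mcmc_control`.
#' @export
mcmcControl <- function(n_pilot = 20L, pilot_length = 5000L,
                        burn_in = 50000L, n_samples = 5000L, thinning = 10L,
                        prior_odds = 10, alpha_prior_sd = 1.0,
                        beta_prior_mean = -1.0, beta_prior_sd = 1.8,
                        seed = 1L) {
    stopifnot(n_pilot >= 0, pilot_length > 0, burn_in >= 0,
              n_samples > 0, thinning > 0, prior_odds > 0,
              alpha_prior_sd > 0, beta_prior_sd > 0)
    structure(list(n_pilot = as.integer(n_pilot),
                   pilot_length = as.integer(pilot_length),
                   burn_in = as.integer(burn_in),
                   n_samples = as.integer(n_samples),
                   thinning = as.integer(thinning),
                   prior_odds = prior_odds,
                   alpha_prior_sd = alpha_prior_sd,
                   beta_prior_mean = beta_prior_mean,
                   beta_prior_sd = beta_prior_sd,
                   seed = as.integer(seed)),
              class = "mcmc_control")
}

#' Locus FST from model effects
#'
#' The F-model decomposes differentiation on the logit scale,
#' \eqn{\mathrm{logit}(F_{ST}^{ij}) = \alpha_i + \beta_j}, so the implied
#' FST is the logistic of the summed effects.
#'
#' @param alpha Locus effect(s).
#' @param beta Population effect(s).
#' @return `1 / (1 + exp(-(alpha + beta)))`, in (0, 1).
#' @examples
#' fstFromEffects(0, 0)    # 0.5
#' fstFromEffects(-2, 0)   # ~0.119
#' @export
fstFromEffects <- function(alpha, beta) {
    stopifnot(all(is.finite(alpha)), all(is.finite(beta)))
    stats::plogis(alpha + beta)
}

#' Beta-binomial marginal log-likelihood of allele counts
#'
#' Marginal likelihood of observing `a` copies of the A allele among `n`
#' called alleles when the population frequency is Beta-distributed around
#' the ancestral frequency `p` with dispersion
#' \eqn{\theta = (1 - F_{ST})/F_{ST}}:
#' \deqn{\log\left[\binom{n}{a}
#'   \frac{B(a + \theta p,\; n - a + \theta(1-p))}{B(\theta p,\;
#'   \theta(1-p))}\right]}
#'
#' @param a A-allele count(s), `0 <= a <= n`.
#' @param n Total called alleles.
#' @param p Ancestral A-allele frequency, strictly in (0, 1).
#' @param theta Dispersion parameter, > 0; as `theta` grows the distribution
#'   approaches Binomial(n, p).
#' @return Log-likelihood, finite for all valid inputs; 0 when `n = 0`.
#' @export
betaBinomialLogLik <- function(a, n, p, theta) {
    if (any(a < 0 | a > n) || any(p <= 0 | p >= 1) || any(theta <= 0))
        stop("domain error: need 0 <= a <= n, 0 < p < 1, theta > 0")
    u <- theta * p
    v <- theta * (1 - p)
    ifelse(n == 0, 0,
           lchoose(n, a) + lbeta(a + u, n - a + v) - lbeta(u, v))
}

#' Bayesian FST-outlier scan of one population pair
#'
#' Runs the reversible-jump MCMC of the beta-binomial F-model on an
#' \linkS4class{AlleleCounts} table restricted to two populations and
#' returns, per locus, the posterior probability that the locus-specific
#' effect alpha is in the model (`gamma`), the posterior error probability
#' (`pep = 1 - gamma`), the q-value (minimum false discovery rate at which
#' the locus becomes significant), and posterior means of alpha and of the
#' locus FST.
#'
#' Loci monomorphic across both populations (or with no called alleles)
#' carry no differentiation information; they are reported with
#' `gamma = 0`, `pep = 1` and are never significant, keeping the output
#' aligned with the input locus list.
#'
#' Given the same `control$seed` the scan is fully deterministic, and
#' because proposal streams are attached to loci through a canonical
#' ordering by SNP id, results do not depend on the storage order of the
#' input rows.
#'
#' @param counts An \linkS4class{AlleleCounts} with exactly 2 populations.
#' @param control An [mcmcControl()] list.
#' @return A `data.frame` with columns `snp_id`, `gamma`, `pep`, `q_value`,
#'   `alpha_mean`, `fst_mean`, rows in input locus order, plus attributes
#'   `beta_mean_post` and `acceptance`.
#' @export
runFstScan <- function(counts, control = mcmcControl()) {
    if (!methods::is(counts, "AlleleCounts"))
        stop("'counts' must be an AlleleCounts object")
    if (ncol(counts) != 2L)
        stop("the pairwise scan needs exactly 2 populations, got ",
             ncol(counts))
    a <- countsA(counts)
    n <- countsTotal(counts)
    ids <- rownames(a)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(a)))

    atot <- rowSums(a)
    ntot <- rowSums(n)
    informative <- ntot > 0L & atot > 0L & atot < ntot

    out <- data.frame(snp_id = ids, gamma = 0, pep = 1, q_value = NA_real_,
                      alpha_mean = 0, fst_mean = NA_real_,
                      stringsAsFactors = FALSE)

    if (any(informative)) {
        idx <- which(informative)
        ord <- idx[order(ids[idx])]  # canonical stream assignment
        res <- .fmodel_mcmc(a[ord, , drop = FALSE], n[ord, , drop = FALSE],
                            control$n_pilot, control$pilot_length,
                            control$burn_in, control$n_samples,
                            control$thinning, control$prior_odds,
                            control$alpha_prior_sd, control$beta_prior_mean,
                            control$beta_prior_sd, control$seed)
        out$gamma[ord] <- res$gamma
        out$pep[ord] <- 1 - res$gamma
        out$alpha_mean[ord] <- res$alpha_mean
        out$fst_mean[ord] <- res$fst_mean
        attr(out, "beta_mean_post") <- stats::setNames(res$beta_mean_post,
                                                       colnames(counts))
        acc <- c(p = res$accept_p, alpha = res$accept_alpha,
                 beta = res$accept_beta, rj = res$accept_rj)
        attr(out, "acceptance") <- acc
        rw <- acc[c("p", "beta")]
        if (any(!is.na(rw) & (rw < 0.01 | rw > 0.9)))
            warning("random-walk acceptance rate outside (0.01, 0.9); ",
                    "consider longer pilot runs")
    }
    # q-values are computed across the informative loci only; uninformative
    # (monomorphic / uncalled) loci are pinned at q = 1 so they can never
    # reach significance
    out$q_value <- rep(1, nrow(out))
    out$q_value[informative] <- computeQValues(out$pep[informative])
    out
}

#' q-values from posterior error probabilities
#'
#' The q-value of a locus is the minimum false discovery rate at which it
#' becomes significant. With posterior error probabilities (PEP, the
#' posterior probability that the locus is neutral) this is the running mean
#' of the sorted PEPs: sort ascending, set the q at rank k to the mean of
#' the k smallest PEPs, and map back to input order. Tied PEPs share the
#' q-value of their last tied rank.
#'
#' @param peps Numeric vector of PEPs in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `peps`;
#'   non-decreasing when `peps` is sorted.
#' @examples
#' computeQValues(c(0.01, 0.03, 0.20))  # 0.01 0.02 0.08
#' @export
computeQValues <- function(peps) {
    if (!length(peps)) return(numeric(0))
    stopifnot(all(peps >= 0 & peps <= 1))
    ord <- order(peps)
    sorted <- peps[ord]
    q_sorted <- cumsum(sorted) / seq_along(sorted)
    # ties share the q of their last tied rank
    last_of_tie <- rev(!duplicated(rev(sorted)))
    q_sorted <- rev(cummin(rev(ifelse(last_of_tie, q_sorted, Inf))))
    q <- numeric(length(peps))
    q[ord] <- q_sorted
    q
}

#' Loci significant at a q-value threshold
#'
#' @param posteriors A data.frame as returned by [runFstScan()] (columns
#'   `snp_id`, `q_value`).
#' @param q_threshold Retention threshold; strictly `q_value <` threshold
#'   retains.
#' @return Character vector of significant SNP ids.
#' @export
significantLoci <- function(posteriors, q_threshold = 0.05) {
    if (!nrow(posteriors)) return(character(0))
    posteriors$snp_id[!is.na(posteriors$q_value) &
                      posteriors$q_value < q_threshold]
}
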