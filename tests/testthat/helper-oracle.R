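# Independent grid-quadrature oracle for the two-population F-model.
#
# Computes exact (up to quadrature error) posterior inclusion probabilities
# P(delta_i = 1 | a, n) and posterior mean population effects by enumerating
# all 2^I inclusion configurations and integrating the beta-binomial
# likelihood over (p_i, alpha_i, beta_1, beta_2) on dense grids. Feasible
# for I <= 3 loci; shares no code with the MCMC sampler.

oracle_bb_ll <- function(a, n, p, s) {
    # np x ns matrix of log BetaBinomial(a | n, theta*p, theta*(1-p)) sans
    # the binomial coefficient, with theta = exp(-s), s = alpha + beta
    if (n == 0) return(matrix(0, length(p), length(s)))
    th <- exp(-pmin(pmax(s, -200), 200))
    u <- outer(p, th)            # np x ns
    v <- outer(1 - p, th)
    lbeta(a + u, n - a + v) - lbeta(u, v)
}

oracle_posterior <- function(a, n, prior_odds = 10, alpha_sd = 1,
                             beta_mean = -1, beta_sd = 1.8,
                             step = 0.25, np = 64, alpha_halfwidth = 4,
                             beta_halfwidth = 7.5) {
    a <- as.matrix(a); n <- as.matrix(n)
    I <- nrow(a)
    stopifnot(ncol(a) == 2, I <= 3)
    ag <- seq(-alpha_halfwidth, alpha_halfwidth, by = step)
    bg <- seq(beta_mean - beta_halfwidth, beta_mean + beta_halfwidth,
              by = step)
    na_ <- length(ag); nb <- length(bg)
    pg <- (seq_len(np) - 0.5) / np
    wa <- stats::dnorm(ag, 0, alpha_sd); wa <- wa / sum(wa)
    wb <- stats::dnorm(bg, beta_mean, beta_sd); wb <- wb / sum(wb)
    sg <- seq(ag[1] + bg[1], ag[na_] + bg[nb], by = step)
    i0 <- which.min(abs(ag))  # index of alpha = 0 within ag

    # per locus: M1[v1, v2] = log integral over (p, alpha); M0 likewise at
    # alpha = 0
    M1 <- vector("list", I); M0 <- vector("list", I)
    for (i in seq_len(I)) {
        EX1 <- exp(oracle_bb_ll(a[i, 1], n[i, 1], pg, sg))
        EX2 <- exp(oracle_bb_ll(a[i, 2], n[i, 2], pg, sg))
        m1 <- matrix(NA_real_, nb, nb)
        for (v1 in seq_len(nb)) {
            A <- sweep(EX1[, (v1 - 1) + seq_len(na_), drop = FALSE], 2, wa,
                       `*`)
            for (v2 in seq_len(nb))
                m1[v1, v2] <- sum(A * EX2[, (v2 - 1) + seq_len(na_),
                                          drop = FALSE])
        }
        M1[[i]] <- log(m1 / np)
        m0 <- (EX1[, (seq_len(nb) - 1) + i0, drop = FALSE] / np)
        M0[[i]] <- log(crossprod(m0,
                                 EX2[, (seq_len(nb) - 1) + i0,
                                     drop = FALSE]))
    }

    lw_b <- outer(log(wb), log(wb), `+`)
    lpi1 <- -log1p(prior_odds)
    lpi0 <- log(prior_odds) + lpi1

    configs <- as.matrix(expand.grid(rep(list(0:1), I)))
    log_ev <- numeric(nrow(configs))
    post_b1 <- post_b2 <- numeric(nrow(configs))
    for (k in seq_len(nrow(configs))) {
        d <- configs[k, ]
        ll <- lw_b
        for (i in seq_len(I))
            ll <- ll + if (d[i] == 1) M1[[i]] else M0[[i]]
        m <- max(ll)
        w <- exp(ll - m)
        log_ev[k] <- m + log(sum(w)) + sum(ifelse(d == 1, lpi1, lpi0))
        post_b1[k] <- sum(rowSums(w) * bg) / sum(w)
        post_b2[k] <- sum(colSums(w) * bg) / sum(w)
    }
    mx <- max(log_ev)
    pk <- exp(log_ev - mx); pk <- pk / sum(pk)
    gamma <- vapply(seq_len(I),
                    function(i) sum(pk[configs[, i] == 1]), numeric(1))
    list(gamma = gamma,
         beta_mean_post = c(sum(pk * post_b1), sum(pk * post_b2)),
         config_probs = pk)
}
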