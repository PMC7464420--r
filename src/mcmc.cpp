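// Reversible-jump MCMC for the beta-binomial F-model.
//
// Model, for locus i and population j with A-allele count a_ij out of n_ij
// called alleles:
//   logit(Fst_ij) = alpha_i + beta_j,  theta_ij = (1 - Fst_ij)/Fst_ij
//   a_ij | p_i, theta_ij ~ BetaBinomial(n_ij, theta_ij p_i, theta_ij (1-p_i))
// Priors: p_i ~ U(0,1); beta_j ~ N(beta_mean, beta_sd^2);
// alpha_i = 0 with prior probability prior_odds/(1+prior_odds), otherwise
// alpha_i ~ N(0, alpha_sd^2). The jump move proposes alpha from a per-locus
// Gaussian tuned during pilot runs (falling back to the prior), so the
// acceptance ratio carries the prior/proposal density ratio.
//
// Random numbers come from self-contained xorshift128+ streams, one per
// locus plus one global stream, all derived from a single master seed; the
// caller fixes the locus order (canonical sort by SNP id), which makes
// results invariant to the storage order of the input.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

struct Stream {
    uint64_t s0, s1;
    explicit Stream(uint64_t seed) {
        // splitmix64 expansion of the (seed, stream) pair
        uint64_t z = seed;
        for (int k = 0; k < 2; ++k) {
            z += 0x9E3779B97F4A7C15ULL;
            uint64_t t = z;
            t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
            t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
            t ^= (t >> 31);
            (k == 0 ? s0 : s1) = t;
        }
        if (s0 == 0 && s1 == 0) s0 = 1;
    }
    uint64_t next() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return s1 + y;
    }
    double unif() {  // strictly inside (0,1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    double norm() {
        double u1 = unif(), u2 = unif();
        return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    }
};

inline double clamp(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// beta-binomial log likelihood without the binomial coefficient (constant
// in all Metropolis ratios)
inline double bb_ll(int a, int n, double p, double ab_sum) {
    if (n == 0) return 0.0;
    double e = clamp(ab_sum, -200.0, 200.0);
    double th = std::exp(-e);  // (1-Fst)/Fst
    double u = th * p, v = th * (1.0 - p);
    return R::lbeta(a + u, n - a + v) - R::lbeta(u, v);
}

inline double dnorm_log(double x, double m, double s) {
    double z = (x - m) / s;
    return -0.5 * z * z - std::log(s) - 0.9189385332046727;
}

struct Welford {
    long cnt = 0;
    double mean = 0.0, m2 = 0.0;
    void add(double x) {
        ++cnt;
        double d = x - mean;
        mean += d / cnt;
        m2 += d * (x - mean);
    }
    double var() const { return cnt > 1 ? m2 / (cnt - 1) : 0.0; }
};

}  // namespace

// [[Rcpp::export(name = ".fmodel_mcmc")]]
Rcpp::List fmodel_mcmc(Rcpp::IntegerMatrix a, Rcpp::IntegerMatrix n,
                       int n_pilot, int pilot_length, int burn_in,
                       int n_samples, int thinning,
                       double prior_odds, double alpha_sd,
                       double beta_mean, double beta_sd, double seed) {
    const int I = a.nrow(), J = a.ncol();
    const double log_pi1 = -std::log1p(prior_odds);            // log P(delta=1)
    const double log_pi0 = std::log(prior_odds) + log_pi1;     // log P(delta=0)

    std::vector<Stream> rng;
    rng.reserve(I + 1);
    for (int i = 0; i <= I; ++i)
        rng.emplace_back(static_cast<uint64_t>(seed) * 0x2545F4914F6CDD1DULL
                         + 0x9E3779B97F4A7C15ULL * (i + 1));
    Stream& grng = rng[I];

    // state
    std::vector<double> x(I), p(I), alpha(I, 0.0);
    std::vector<int> delta(I, 0);
    std::vector<double> beta(J, beta_mean);
    for (int i = 0; i < I; ++i) {
        double atot = 1.0, ntot = 2.0;
        for (int j = 0; j < J; ++j) { atot += a(i, j); ntot += n(i, j); }
        p[i] = clamp(atot / ntot, 0.01, 0.99);
        x[i] = std::log(p[i] / (1.0 - p[i]));
    }
    std::vector<double> ll(static_cast<size_t>(I) * J);
    auto LL = [&](int i, int j) -> double& { return ll[i * J + j]; };
    for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
            LL(i, j) = bb_ll(a(i, j), n(i, j), p[i], alpha[i] + beta[j]);

    // adaptive proposal scales and jump proposals
    std::vector<double> sd_p(I, 0.6), sd_a(I, 0.4);
    std::vector<double> sd_b(J, 0.25);
    std::vector<double> jump_m(I, 0.0), jump_s(I, alpha_sd);
    std::vector<Welford> alpha_track(I);
    std::vector<long> acc_p(I, 0), att_p(I, 0), acc_a(I, 0), att_a(I, 0);
    std::vector<long> acc_b(J, 0), att_b(J, 0);
    long acc_rj = 0, att_rj = 0;

    // accumulators
    std::vector<double> sum_delta(I, 0.0), sum_alpha(I, 0.0), sum_fst(I, 0.0);
    std::vector<double> sum_beta(J, 0.0);
    long kept = 0;

    auto iterate = [&](bool pilot) {
        for (int i = 0; i < I; ++i) {
            Stream& s = rng[i];
            // 1. ancestral frequency, random walk on the logit scale;
            //    uniform prior on p contributes the Jacobian p(1-p)
            {
                double xn = clamp(x[i] + sd_p[i] * s.norm(), -14.0, 14.0);
                double pn = logistic(xn);
                double la = 0.0;
                double ll_new[8];
                for (int j = 0; j < J; ++j) {
                    ll_new[j] = bb_ll(a(i, j), n(i, j), pn, alpha[i] + beta[j]);
                    la += ll_new[j] - LL(i, j);
                }
                la += std::log(pn * (1.0 - pn)) - std::log(p[i] * (1.0 - p[i]));
                ++att_p[i];
                if (std::log(s.unif()) < la) {
                    x[i] = xn; p[i] = pn;
                    for (int j = 0; j < J; ++j) LL(i, j) = ll_new[j];
                    ++acc_p[i];
                }
            }
            // 2. locus effect, random walk (only when included)
            if (delta[i]) {
                double an = alpha[i] + sd_a[i] * s.norm();
                double la = 0.0;
                double ll_new[8];
                for (int j = 0; j < J; ++j) {
                    ll_new[j] = bb_ll(a(i, j), n(i, j), p[i], an + beta[j]);
                    la += ll_new[j] - LL(i, j);
                }
                la += dnorm_log(an, 0.0, alpha_sd)
                    - dnorm_log(alpha[i], 0.0, alpha_sd);
                ++att_a[i];
                if (std::log(s.unif()) < la) {
                    alpha[i] = an;
                    for (int j = 0; j < J; ++j) LL(i, j) = ll_new[j];
                    ++acc_a[i];
                }
            }
            // 3. reversible jump between alpha = 0 and alpha free
            {
                ++att_rj;
                double ll_new[8];
                if (!delta[i]) {
                    double as = jump_m[i] + jump_s[i] * s.norm();
                    double la = 0.0;
                    for (int j = 0; j < J; ++j) {
                        ll_new[j] = bb_ll(a(i, j), n(i, j), p[i], as + beta[j]);
                        la += ll_new[j] - LL(i, j);
                    }
                    la += log_pi1 - log_pi0
                        + dnorm_log(as, 0.0, alpha_sd)
                        - dnorm_log(as, jump_m[i], jump_s[i]);
                    if (std::log(s.unif()) < la) {
                        delta[i] = 1; alpha[i] = as;
                        for (int j = 0; j < J; ++j) LL(i, j) = ll_new[j];
                        ++acc_rj;
                    }
                } else {
                    double la = 0.0;
                    for (int j = 0; j < J; ++j) {
                        ll_new[j] = bb_ll(a(i, j), n(i, j), p[i], beta[j]);
                        la += ll_new[j] - LL(i, j);
                    }
                    la += log_pi0 - log_pi1
                        + dnorm_log(alpha[i], jump_m[i], jump_s[i])
                        - dnorm_log(alpha[i], 0.0, alpha_sd);
                    if (std::log(s.unif()) < la) {
                        delta[i] = 0; alpha[i] = 0.0;
                        for (int j = 0; j < J; ++j) LL(i, j) = ll_new[j];
                        ++acc_rj;
                    }
                }
            }
            if (pilot && delta[i]) alpha_track[i].add(alpha[i]);
        }
        // 4. population effects
        for (int j = 0; j < J; ++j) {
            double bn = beta[j] + sd_b[j] * grng.norm();
            double la = dnorm_log(bn, beta_mean, beta_sd)
                - dnorm_log(beta[j], beta_mean, beta_sd);
            std::vector<double> ll_new(I);
            for (int i = 0; i < I; ++i) {
                ll_new[i] = bb_ll(a(i, j), n(i, j), p[i], alpha[i] + bn);
                la += ll_new[i] - LL(i, j);
            }
            ++att_b[j];
            if (std::log(grng.unif()) < la) {
                beta[j] = bn;
                for (int i = 0; i < I; ++i) LL(i, j) = ll_new[i];
                ++acc_b[j];
            }
        }
    };

    auto tune = [](double& sd, long acc, long att) {
        if (att == 0) return;
        double r = static_cast<double>(acc) / att;
        if (r > 0.45) sd *= 1.25;
        else if (r < 0.25) sd *= 0.8;
        sd = clamp(sd, 1e-3, 10.0);
    };

    if (J > 8) Rcpp::stop("at most 8 populations are supported per scan");

    // pilot runs: adapt random-walk scales and the jump proposal
    for (int r = 0; r < n_pilot; ++r) {
        for (int it = 0; it < pilot_length; ++it) iterate(true);
        for (int i = 0; i < I; ++i) {
            tune(sd_p[i], acc_p[i], att_p[i]);
            tune(sd_a[i], acc_a[i], att_a[i]);
            acc_p[i] = att_p[i] = acc_a[i] = att_a[i] = 0;
            if (alpha_track[i].cnt >= 20) {
                jump_m[i] = alpha_track[i].mean;
                jump_s[i] = std::max(std::sqrt(alpha_track[i].var()), 0.25);
            }
        }
        for (int j = 0; j < J; ++j) {
            tune(sd_b[j], acc_b[j], att_b[j]);
            acc_b[j] = att_b[j] = 0;
        }
    }
    acc_rj = att_rj = 0;

    for (int it = 0; it < burn_in; ++it) iterate(false);

    for (int smp = 0; smp < n_samples; ++smp) {
        for (int t = 0; t < thinning; ++t) iterate(false);
        for (int i = 0; i < I; ++i) {
            sum_delta[i] += delta[i];
            sum_alpha[i] += alpha[i];
            double f = 0.0;
            for (int j = 0; j < J; ++j) f += logistic(alpha[i] + beta[j]);
            sum_fst[i] += f / J;
        }
        for (int j = 0; j < J; ++j) sum_beta[j] += beta[j];
        ++kept;
        if ((smp & 255) == 0) Rcpp::checkUserInterrupt();
    }

    Rcpp::NumericVector gamma(I), alpha_mean(I), fst_mean(I);
    for (int i = 0; i < I; ++i) {
        gamma[i] = sum_delta[i] / kept;
        alpha_mean[i] = sum_alpha[i] / kept;
        fst_mean[i] = sum_fst[i] / kept;
    }
    Rcpp::NumericVector beta_post(J);
    double acc_p_all = 0, att_p_all = 0, acc_a_all = 0, att_a_all = 0;
    for (int i = 0; i < I; ++i) {
        acc_p_all += acc_p[i]; att_p_all += att_p[i];
        acc_a_all += acc_a[i]; att_a_all += att_a[i];
    }
    double acc_b_all = 0, att_b_all = 0;
    for (int j = 0; j < J; ++j) {
        beta_post[j] = sum_beta[j] / kept;
        acc_b_all += acc_b[j]; att_b_all += att_b[j];
    }
    return Rcpp::List::create(
        Rcpp::Named("gamma") = gamma,
        Rcpp::Named("alpha_mean") = alpha_mean,
        Rcpp::Named("fst_mean") = fst_mean,
        Rcpp::Named("beta_mean_post") = beta_post,
        Rcpp::Named("accept_p") = att_p_all > 0 ? acc_p_all / att_p_all : NA_REAL,
        Rcpp::Named("accept_alpha") = att_a_all > 0 ? acc_a_all / att_a_all : NA_REAL,
        Rcpp::Named("accept_beta") = att_b_all > 0 ? acc_b_all / att_b_all : NA_REAL,
        Rcpp::Named("accept_rj") = att_rj > 0 ? static_cast<double>(acc_rj) / att_rj : NA_REAL);
}
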