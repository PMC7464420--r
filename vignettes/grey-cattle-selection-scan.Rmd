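---
title: "Multi-cohort FST-outlier scans for convergent selection signatures"
author: "greyscan package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort FST-outlier scans for convergent selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyscan)
```

## The scientific problem

Fifteen European and Mediterranean cattle breeds share a striking coat-colour
syndrome: calves are born fawn and turn grey within months, skin stays
pigmented, and bulls are darker than cows. A way to look for the genomic
basis of such a shared phenotype is to contrast each grey breed against
reference breeds with solid or piebald coats (Angus, Charolais, Holstein,
Limousin) and ask which SNPs are *recurrently* more differentiated than
drift alone would explain. With 15 test breeds and 4 references there are
60 pairwise contrasts; a locus that keeps surfacing across contrasts — the
same marker, against different genetic backgrounds — is a candidate for
convergent selection on the shared phenotype rather than breed-specific
history.

greyscan implements that whole design as a tested pipeline: PED/MAP input,
PLINK-style quality control, a Bayesian F-model FST-outlier test per breed
pair, q-value retention, cross-contrast occurrence aggregation, ±250 kbp
window construction, and gene annotation — plus a synthetic genotype
generator so every stage can be exercised and calibrated without access to
the original genotypes.

## The F-model and its outlier test

For locus $i$ in population $j$, let $a_{ij}$ be the count of the A allele
among $n_{ij}$ successfully genotyped alleles. The F-model treats the
population allele frequency $\tilde p_{ij}$ as a Balding–Nichols draw
around an ancestral frequency $p_i$:

$$\tilde p_{ij} \sim \mathrm{Beta}\left(\theta_{ij} p_i,\;
\theta_{ij}(1 - p_i)\right), \qquad
\theta_{ij} = \frac{1 - F_{ST}^{ij}}{F_{ST}^{ij}},$$

so that $\mathrm{Var}[\tilde p_{ij}] = F_{ST}^{ij}\, p_i (1-p_i)$.
Integrating $\tilde p_{ij}$ out gives a beta-binomial marginal likelihood
for the counts. Differentiation is decomposed on the logit scale,

$$\mathrm{logit}\, F_{ST}^{ij} = \alpha_i + \beta_j,$$

where $\beta_j$ captures the demography a population shares across loci
(drift since divergence) and $\alpha_i$ is a locus-specific departure —
positive $\alpha_i$ means locus $i$ is more differentiated than the genome
average, the signature of diversifying selection.

The outlier test is Bayesian model choice per locus: a neutral model with
$\alpha_i = 0$ against a selection model with
$\alpha_i \sim \mathcal N(0, \sigma_\alpha^2)$. A reversible-jump MCMC
samples the joint posterior of $(\alpha, \delta, \beta, p)$, where
$\delta_i$ is the inclusion indicator; the posterior inclusion probability
$\gamma_i = P(\delta_i = 1 \mid \text{data})$ and its complement, the
posterior error probability $\mathrm{PEP}_i = 1 - \gamma_i$, drive
inference. The q-value of a locus — the minimum false discovery rate at
which it becomes significant — is the running mean of the PEPs sorted in
increasing order. Loci with $q < 0.05$ are retained per contrast.

### Priors and default settings

| Parameter | Default | Meaning |
|---|---|---|
| `prior_odds` | 10 | prior odds for the neutral model; about 1 locus in 11 non-neutral a priori |
| `alpha_prior_sd` | 1.0 | spread of locus effects under selection (logit scale) |
| `beta_prior_mean`, `beta_prior_sd` | −1.0, 1.8 | population-effect prior; mean −1 centres per-population FST near 0.27 with wide uncertainty |
| `n_pilot`, `pilot_length` | 20 × 5000 | adaptation runs for the proposal scales |
| `burn_in` | 50,000 | discarded iterations after adaptation |
| `n_samples`, `thinning` | 5000, 10 | retained posterior samples |
| `q_threshold` | 0.05 | per-contrast retention (strict `<`) |
| `min_count` | 15 (25% of 60) | cross-contrast occurrence threshold (inclusive) |
| `half_width` | 250 kbp | window flank; LD in cattle rarely extends past 500 kbp |

All are exposed through `mcmcControl()` and `pipelineConfig()`. The chain
defaults mirror the reference implementation of this test; the analyses in
this package's own test-suite shorten them (typically 5 pilots × 200, 800
burn-in, 600 samples at thinning 5) after checking on small instances that
the shortened chains agree with both long chains and exact quadrature to
within about 0.01 in $\gamma$.

### Numerical design

- **Sampler.** The per-locus updates (ancestral frequency on the logit
  scale, locus effect, reversible jump) and per-population updates are
  Gaussian random walks whose scales are tuned during pilot runs toward
  acceptance rates in [0.25, 0.45], then frozen to preserve detailed
  balance. The jump move proposes $\alpha$ from a per-locus Gaussian fitted
  to the pilot samples (falling back to the prior), with the
  prior-to-proposal density ratio in the acceptance probability.
- **Reproducibility.** One master seed drives self-contained xorshift128+
  streams, one per locus plus one global stream. Streams attach to loci
  through a canonical ordering by SNP id, so results are exactly invariant
  to the storage order of the input — a property the tests assert
  bit-for-bit.
- **Degenerate loci.** Loci monomorphic across both populations of a pair
  (possible after subsetting despite global MAF filtering) carry no
  differentiation information: they are reported with $\gamma = 0$,
  $\mathrm{PEP} = 1$, $q = 1$, and can never be significant, keeping every
  pair's locus list aligned with the panel.
- **Allele orientation.** The A allele is whichever character appears first
  at a locus in the source file. The beta-binomial likelihood is symmetric
  under $a \to n - a$, $p \to 1 - p$, so orientation cannot affect results;
  a test checks this by relabeling.
- **Validation oracle.** On instances of up to 3 loci the posterior is also
  computed by brute-force quadrature over $(p_i, \alpha_i, \beta_1,
  \beta_2)$ on dense grids, enumerating all inclusion configurations. The
  MCMC agrees with this independent oracle to within 0.03 in $\gamma$
  (observed agreement is better than 0.01); the oracle is grid-converged
  (doubling resolution changes nothing at four decimals).

## Quality control

`runQC()` applies, in order: restriction to autosomes, individual
missingness (`--mind 0.1` semantics: removed only when missingness strictly
exceeds the threshold), locus call rate (`--geno 0.1`, same strictness),
and minor allele frequency (`--maf 0.01`: kept when MAF ≥ 0.01). The
operational semantics follow the PLINK commands rather than their loose
prose glosses ("call rate ≤ 90%"), because the commands are what an
analysis actually executes; individuals are filtered before locus
statistics so call rate and MAF refer to the retained individual set. Each
filter is a projection (idempotent), and the QC report conserves counts on
both axes.

## The synthetic generator: what it emulates, and what not

`simulatePanel()` produces a panel with the statistical structure the scan
assumes. Ancestral frequencies are uniform on (0.05, 0.95); each breed gets
a population effect $\beta_j \sim \mathcal N(-2, 0.3^2)$, i.e. a
differentiation level near $\mathrm{plogis}(-2) \approx 0.12$ — a realistic
between-breed FST for cattle; per-breed frequencies are Balding–Nichols
draws; genotypes are Binomial(2, freq) under Hardy–Weinberg; 2% of calls
are dropped at random. At the 2% of loci designated as convergently
selected, every *grey* breed draws its frequency around a shared derived
frequency $p_i' = \mathrm{clamp}(p_i + 0.5,\, 0.05,\, 0.95)$ with elevated
differentiation $\mathrm{plogis}(\alpha_{sel} + \beta_j)$,
$\alpha_{sel} = 2.5$. A shared derived frequency — rather than independent
high-FST draws per breed — is what makes the signal *convergent*: the same
locus shifted the same way in every grey breed, against every reference.

The default panel (19 breeds × 24 individuals, 1000 loci) keeps the full
60-scan analysis tractable in minutes at shortened chains; the generator is
model-matched to the scan (the likelihood is exactly the generator's
distribution), so calibration results are about information content, not
model misspecification.

What the generator does *not* emulate: linkage disequilibrium between loci
(draws are independent, so window-level clustering of real sweeps is
absent), ascertainment bias of array SNPs, related individuals, and
genotyping error beyond missingness. Passing calibration tests therefore
demonstrates the statistical machinery is correct and calibrated under the
model's own assumptions — not that real-data power equals synthetic power.

## What the calibration shows — honestly

Two properties are checked end-to-end on synthetic panels:

- **False-discovery control.** On a fully neutral panel the fraction of
  loci reaching $q < 0.05$ stays within binomial noise of zero, and no
  neutral locus survives the ≥25% occurrence rule. This holds comfortably.
- **Recovery of convergently selected loci.** Under the default generator
  conditions, recovery through the full pipeline is *partial and highly
  replicate-dependent* (between zero and roughly a third of truly selected
  loci across the seeds we ran; the realized population effects and
  ancestral frequencies of a replicate move many loci across the
  detectability boundary together). The reason is quantitative and
  verifiable by exact quadrature: with 24 individuals per breed and prior
  odds of 10, a single contrast only reaches $q < 0.05$ when the realized
  frequency contrast is near-fixed (a Bayes factor around 200 — $\gamma
  \approx 0.95$ — requires something like 48/48 vs 4/48 alleles). Selected
  loci with high ancestral frequency receive only a small derived shift
  ($p' - p = 0.95 - p$ when $p > 0.45$), and the Balding–Nichols draw at
  $F_{ST} \approx 0.62$ is U-shaped, so many grey breeds realise
  frequencies indistinguishable from the reference at this sample size.
  Those loci accumulate occurrence counts just below the 15-of-60 bar.
  This is a property of the simulated information content, not a sampler
  defect — the sampler matches exact quadrature wherever quadrature is
  feasible. The corresponding acceptance check states the stronger (≥80%)
  expectation and is allowed to fail rather than having the conditions
  tuned until it passes.

## Windows, intervals and annotation

Retained SNPs become ±250 kbp windows (1-based inclusive, clamped at 1;
clamping at chromosome ends is available when lengths are supplied, but the
published coordinates never need it). Overlapping or book-ended windows can
be merged into non-redundant regions (`mergeWindows()`, union-exact by
construction and checked against a base-pair bitmap oracle); the primary
report keeps per-SNP windows unmerged, matching the published table layout,
with merging offered as a separate view. `delimitedInterval()` returns the
flankless span from the outermost SNPs of a cluster — this is how the
2.69 Mb BTA14 interval bounded by BTB-01532239 and Hapmap27934-BTC-065223
arises from its nine recurrent SNPs. Gene annotation accepts BED (0-based
half-open, converted on input) or GFF3 (1-based, `gene` rows); a gene is
reported when it shares at least one base with a window, irrespective of
strand.

## Design choices on open points

- **Occurrence threshold form.** The threshold is stated both as an
  absolute count (15) and a fraction (25%); `applyOccurrenceThreshold()`
  accepts either, and the absolute count wins when both are set.
- **Filter order.** Whether MAF was applied before or after individual
  removal is not documented for the original analysis; the tool-default
  order (individuals first) is adopted, since locus statistics should
  describe the genotypes actually analysed.
- **Per-pair monomorphic loci.** Treated as never-significant rather than
  dropped, so occurrence counting needs no per-pair locus bookkeeping.
- **Chain settings.** The original analysis does not report its chain
  settings; tool defaults are adopted and everything is configurable.

## Known limitations

- The balancing-selection side of the test (negative-$\alpha$-only
  reporting) and multiallelic/dominant data are out of scope.
- Convergence diagnostics are limited to acceptance-rate logging; the
  defaults are conservative, but unusually structured data may warrant
  longer chains.
- Coordinates are assumed to be in the reporting assembly already; no
  liftover is performed.
- The generator's independence across loci means window-level analyses
  (merging, delimited intervals) are exercised on real coordinates from
  the packaged candidate table rather than on simulated LD structure.
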