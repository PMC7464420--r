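Package: greyscan
Title: Multi-Cohort FST-Outlier Selection-Signature Scans for SNP-Array Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects convergent selection signatures across many breed
    contrasts from medium-density SNP-array genotypes. Implements PED/MAP
    input, PLINK-style quality control, a Bayesian F-model FST-outlier test
    with reversible-jump MCMC (posterior inclusion probabilities, posterior
    error probabilities and q-values), aggregation of significant loci across
    all test-by-reference breed pairs with a multiple-occurrence threshold,
    expansion of retained SNPs into flanking genomic windows, and gene
    annotation of the resulting regions. A Balding-Nichols synthetic genotype
    generator with convergently selected loci supports power and false
    discovery calibration without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    rlang,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Bayesian, Genetics
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'bayescan.R'
    'genotype-io.R'
    'multicohort.R'
    'pipeline.R'
    'quality-control.R'
    'regions.R'
    'simulate.R'
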