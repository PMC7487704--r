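Package: CNPmix
Title: Hierarchical Bayesian Copy Number Genotyping Across Latent Batches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genotyping of copy number polymorphisms from SNP-array summaries
    in large case-control studies. Discovers latent batch effects at each CNV
    region by recursively merging chemistry plates with indistinguishable
    empirical distribution functions, fits hierarchical Bayesian mixtures of
    t-distributions across the estimated batches by Gibbs sampling, maps
    mixture components to integer copy numbers using B allele frequencies
    through a beta-binomial likelihood, and propagates copy number uncertainty
    into a Bayesian logistic regression for disease risk with a spike indicator
    for the probability of association. Includes GC and spatial LOESS
    correction of log2 R ratios, CNV region consolidation, Chib marginal
    likelihoods for model comparison, posterior predictive checks, and a
    synthetic cohort generator with plate-structured batch distortions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'batch.R'
    'genotype.R'
    'io.R'
    'mixture.R'
    'select.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
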