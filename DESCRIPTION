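Package: vafit
Title: Additive Genetic Variance for Fitness from Evolve-and-Resequence
    Allele-Frequency Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the additive genetic variance for relative fitness
    (VA) in a base population from replicated genome-wide allele-frequency
    changes observed in evolve-and-resequence experiments.  Implements the
    genotype-dosage diversity matrix L and its gametic/nongametic
    decomposition, the predicted decay of L under drift and recombination,
    a whitening projection of allele-frequency changes onto the non-null
    subspace of L, and a restricted maximum likelihood (REML) linear mixed
    model for the distribution of average effects, with a bias-corrected
    VA estimator and an optional pool-seq sampling-error covariance.  A
    self-contained forward-time Wright-Fisher simulator with a gamma
    mixture of fitness effects and dominance, and a pool-seq read
    simulator, support validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
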