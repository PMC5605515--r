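Package: photodiel
Title: Diel-Activity Inference from Adaptive Evolution of Phototransduction Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers ancestral diel activity patterns (diurnal, nocturnal,
    cathemeral) from signatures of episodic positive selection in cone- and
    rod-expressed phototransduction genes. Provides a Goldman-Yang codon
    substitution engine with site-class mixtures and maximum-likelihood
    fitting, branch and branch-site likelihood ratio tests with Bayes
    empirical Bayes site identification, a BUSTED-style episodic selection
    test, a RELAX-style selection-intensity test, a rule-based mapping of
    per-branch selection signals to diel states with propagation over a
    focal-lineage tree, marginal empirical-Bayes ancestral amino-acid
    reconstruction with opsin spectral-tuning annotation in bovine-rhodopsin
    numbering, and simulators that generate codon and amino-acid alignments
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
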