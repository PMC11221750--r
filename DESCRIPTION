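Package: admixqc
Title: Ancestry Estimation and Phase-Switch Quality Control for
    Two-Population Admixed Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying admixture between two divergent source
    populations in a pedigreed colony: Weir-Cockerham F_ST estimation and
    ancestry-informative-marker (AIM) panel design with windowing and LD
    pruning, supervised and unsupervised two-way global ancestry estimation
    by maximum likelihood, a two-state hidden Markov model for local
    ancestry with RFMix-style msp input/output, detection and correction
    ("unkinking") of phase switch errors using F1 hybrids, trio Mendelian
    local-ancestry auditing, pedigree-label auditing, and recombination-map
    conversion between rate, PLINK and SHAPEIT formats. Includes a
    pedigree-aware simulator of phased two-population genotypes with known
    ancestry-tract truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
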