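Package: paleohybrid
Title: Inference of Ancient Allopolyploidization from Gene Tree Discordance,
    Ks Distributions and Site Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discriminating ancient allopolyploid
    (hybrid) origin of a clade from incomplete lineage sorting. Implements
    ortholog filtering with redundancy clustering and a substitution
    saturation screen, outgroup rooting and classification of gene trees by
    the focal clade's position relative to two parental superclades,
    Nei-Gojobori (1986) Ks/Ka estimation with a high-identity redundancy
    cutoff and Gaussian-mixture peak detection, an invariant-based
    site-pattern test for hybridization with estimation of the inheritance
    probability gamma, a one-reticulation triplet pseudo-likelihood network
    fit, and fossil-calibrated strict-clock dating with a split-time
    concordance diagnostic. A multispecies-coalescent simulator on a
    one-reticulation species network generates all inputs, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape (>= 5.0),
    phangorn,
    Biostrings,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
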