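Package: viabench
Title: Benchmarking Viability Profiling by PMA Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to benchmark propidium monoazide (PMA) viability
    sequencing of microbial communities. Provides a generative simulator of
    live/dead communities under PMA treatment with 16S amplicon and qPCR
    readouts, deterministic post-treatment composition expectations for
    designed mixtures, the spike-in PMA efficacy statistic built from the
    four-arm (spike x treatment) factorial, per-taxon fold-change ranking of
    PMA-responsive and PMA-resilient taxa, and the compositional statistics
    (genus collapsing, prevalence/abundance filtering, Bray-Curtis
    dissimilarity, principal coordinate analysis, permutational ANOVA) used
    to quantify treatment effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
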