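Package: gsaverse
Title: Analysis-Choice Multiverse and Overoptimism in Gene Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify how much the many defensible analysis choices
    in gene set analysis (GSA) of RNA-seq data can be exploited to produce
    overoptimistic results. Provides a synthetic count-data generator with
    block-correlated negative-binomial genes and sample-label permutation
    nulls, self-contained implementations of the main GSA method archetypes
    (hypergeometric overrepresentation analysis, sample-permutation and
    preranked gene set enrichment analysis, and a gene-frequency-weighted
    functional class scoring method), a formal model of the analysis choice
    space, a greedy stepwise optimizer that tweaks one choice at a time
    toward a stated goal while recording a full audit trail, and an
    experiment layer that enumerates study settings and summarizes the
    optimized-versus-default gap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
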