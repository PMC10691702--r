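Package: mlcoexp
Title: Multilayer Gene Co-Expression Community Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection in multilayer gene co-expression correlation
    matrices. Builds per-tissue Pearson correlation layers from TPM expression
    tables with empirical interlayer couplings over shared donors, scores
    partitions with a multilayer modularity defined against the maximum-entropy
    configuration model for correlation matrices, maximizes it with an iterated
    generalized Louvain engine and consensus clustering, selects the resolution
    parameter with a one-dimensional CHAMP sweep, assesses community
    significance with analytic moments of the null intralayer weight, classifies
    communities as tissue specialists or generalists, and tests detected gene
    groups for physical clustering on chromosomes and for shared cis-eQTL SNPs.
    Includes a synthetic-data generator with planted community structure for
    validation.
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
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
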