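Package: owscore
Title: Optimally Weighted Score Tests for Rare-Variant Association in General Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective score tests for association between rare variants in a
    genomic region and a quantitative trait measured in general pedigrees. The
    statistics treat traits as fixed and genotypes as random, so family
    ascertainment on phenotype does not bias inference. Implements the optimally
    weighted score test (OW-score), whose weights maximise the weighted score
    statistic, and the fixed-weight family including the Madsen-Browning weighted
    comparator (WS-score). Kinship matrices are computed from pedigree structure
    by the standard recursion; the null distribution of the OW-score statistic is
    approximated by a moment-matched scaled chi-square with an optional
    chi-square-mixture cross-check via characteristic-function inversion. A
    gene-dropping pedigree simulator and an evaluation harness estimate empirical
    type I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
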