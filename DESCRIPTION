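Package: credissect
Title: Multi-Scale Dissection of Enhancer Sequence Function from MPRA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-scale functional dissection of cis-regulatory
    elements (CREs) with massively parallel reporter assays (MPRAs). Implements
    barcode-dictionary filtering and RNA/DNA activity quantification, multi-hit
    saturation-mutagenesis variant-effect estimation, position-specific
    binding-model affinity scanning and TFBS anchor construction, multi-size
    sub-tile design with synergy and positional analyses, pairwise TFBS
    epistasis against a multiplicative null, greedy model-guided enhancer
    compaction with activity-size Pareto fronts, and TFBS-anchored enhancer
    derivatization (reconstitution, random deposition, synthetic thripsis).
    A seed-deterministic synthetic-data generator with recorded ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
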