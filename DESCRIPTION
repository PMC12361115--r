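Package: nuoscan
Title: Genomic-Context Filtering of Profile-HMM Hits and Respiratory
    Complex Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes profile-HMM homology searches against prokaryotic
    proteomes into high-confidence annotations of multi-subunit respiratory
    complexes, with NADH:quinone oxidoreductase (Complex I, the 14-subunit
    Nuo operon) as the shipped default scheme. Hits are grouped into
    operon-like clusters by intergenic distance and strand, per-subunit
    e-value cutoffs are derived from kernel density estimates of
    cluster-segregated score distributions, protein-length outliers are
    removed, gene fusions are resolved from domain envelopes, and each genome
    is classified into a complex variant (complete, fused, complex-like,
    incomplete, absent). Includes assembly N50 quality categories,
    species-level aggregation, chi-square association tests between variants
    and metabolic lifestyles, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
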