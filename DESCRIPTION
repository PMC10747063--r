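Package: histoneptm
Title: Compositional Quantification of Histone PTM Peptidoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream quantification of bottom-up histone proteomics data:
    converts peptidoform peak-area tables into per-peptide modification-form
    compositions, estimates H3.1/H3.3 variant proportions from their unique
    K27-R40 peptides, marginalises co-modification states into site-level
    mark abundances (variant-resolved and variant-weighted), and summarises
    acetylation degrees. Statistics follow Aitchison's compositional
    methodology: multiplicative zero replacement, two-part additive log-ratio
    (log2) transformation with Student t-tests and a two-tier significance
    scheme, pivot (isometric log-ratio) coordinates, and Euclidean
    average-linkage hierarchical clustering of sample PTM profiles. A
    synthetic peak-area generator emulating a seedling/callus study design
    (log-normal intensity noise, abundance-ranked dropout) makes every stage
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
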