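Package: trapclient
Title: Label-Free Proteomics Differential Abundance and Signal-Peptide
    Feature Analysis for TRAP/Sec61 Client Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for calling clients of the Sec61 translocon and the
    translocon-associated protein (TRAP) complex from label-free quantitative
    proteomics of siRNA knockdown experiments. Implements two-case missing
    value imputation (downshifted bottom-tail draws for fully missing
    proteins, local least squares regression otherwise), quantile
    normalization, per-contrast unpaired tests with permutation-based false
    discovery rate control, and intersection of the targeting-siRNA contrasts
    into negatively and positively affected protein sets. Downstream tools
    score signal peptides and transmembrane helices by glycine-plus-proline
    content and Kyte-Doolittle hydrophobicity, compare client and background
    cohorts by rank tests, and compute annotation-category enrichment
    factors. A seeded synthetic-data generator emulates knockdown LFQ
    datasets with intensity-dependent missingness for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
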