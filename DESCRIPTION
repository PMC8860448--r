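Package: proxcomp
Title: Compartment-Resolved Proximity-Labeling Proteomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of APEX2 proximity-labeling proteomics across neuronal
    subcellular compartments: total-intensity normalization of label-free
    quantification tables, Welch t-test differential abundance with
    Benjamini-Hochberg FDR control, multi-rule compartment filtering cascades
    that integrate single-cell RNA-seq expression bounds and specificity,
    subsampling-equalized single-cell differential expression and marker-gene
    selection from UMI counts, slice/synaptosome concordance, marker-protein
    localization calls, hypergeometric over-representation analysis, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    scran
Config/testthat/edition: 3
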