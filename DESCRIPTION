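Package: itraqdiff
Title: Differential Protein Expression from Pooled Isobaric-Tag Reporter Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled multiplexed isobaric-tag (iTRAQ/TMT)
    proteomics with a small number of reporter channels per group: reference
    normalization and peptide-to-protein rollup, two-step peptide-distribution
    qualification of proteins (control-channel comparability, then
    patient-versus-control difference) with Benjamini-Hochberg FDR control,
    derivation of a data-driven control/patient ratio threshold, candidate
    selection and SwissProt-level deduplication, evidence-tier categorization
    of network-analysis scores, interactome neighborhood queries with
    SIF/GraphML subnetwork export, Western-blot validation statistics, and a
    seeded synthetic-data generator with planted fold changes for method
    evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
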