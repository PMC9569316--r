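Package: secshift
Title: Interactome Rewiring Analysis for Co-Fractionation and Isothermal
    Shift Proteomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting growth phase-dependent rewiring
    of protein-protein and protein-metabolite interactions from
    size-exclusion co-fractionation mass spectrometry (CF-MS) and isothermal
    shift assay (iTSA) experiments. Provides elution-profile normalization,
    peak deconvolution and molecular-weight calibration; median-normalized
    differential protein abundance testing; per-temperature differential
    thermal stability calls; Manhattan-distance and permutation-based
    differential fractionation detection; protein-bound versus free
    metabolite pool analytics; co-fractionation Pearson correlation networks
    with Louvain community detection; dipeptide-pathway interaction-rate
    matrices; and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
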