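Package: synercomb
Title: Drug-Combination Synergy Scoring, Sparse-Sampling PK and Xenograft
    Efficacy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of two-drug checkerboard viability screens and the
    companion preclinical in-vivo readouts. Scores dose-response matrices
    against the Bliss independence, Loewe additivity, highest-single-agent
    (HSA) and zero-interaction-potency (ZIP) reference models (cell-wise and
    mean delta scores), fits the MuSyC four-state dose-response surface and
    derives its potency (alpha), efficacy (beta) and cooperativity (gamma)
    synergy metrics, gates fits by R-squared and aggregates scores across
    models, timepoints and assays with threshold-based interaction calls.
    Also provides non-compartmental pharmacokinetics for sparse destructive
    sampling designs (linear trapezoidal AUC, Cmax, Tmax from pseudo-profiles)
    and tumour-growth-inhibition computation for xenograft efficacy studies,
    plus a seeded synthetic-data generator for every input format so the full
    pipeline is testable without raw assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr
Config/testthat/edition: 3
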