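Package: pheoscreen
Title: Quantitative High-Throughput Screen Analysis and Drug Combination
    Triage for Metastatic Pheochromocytoma Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for drug-repurposing screens in
    pheochromocytoma/paraganglioma cell models: plate normalization against
    DMSO and positive-control wells, four-parameter logistic curve fitting,
    Inglese-style concentration-response curve classification and activity
    triage, therapeutic-category enrichment, cross-species drug-target
    expression correlation, drug-target network construction with
    eccentricity-centrality hub ranking, and Chou-Talalay median-effect
    synergy quantification (combination index and dose-reduction index).
    Includes a synthetic-data module that generates every pipeline input
    with planted ground truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
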