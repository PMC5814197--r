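Package: trajscreen
Title: Stage-Trajectory Screening of Continuously Regulated Genes in Tumor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens genes that are continuously up- or down-regulated across an
    ordered series of disease stages (e.g. normal tissue through primary tumor
    stages to distant metastases), partitions out the genes that deviate from the
    trend at each stage transition, filters stage-wise gene sets by Gene Ontology
    cellular-component terms, tests deviated sets for biological-process
    over-representation with a hypergeometric test, and analyses protein-protein
    interaction networks of the screened genes with an MCODE-style molecular
    complex detection algorithm, degree-ranged hub subnetworks and deterministic
    key signal-chain extraction. Includes a synthetic-data generator that
    emulates the seven-stage colorectal-cancer study design the screen assumes,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
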