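Package: pupomics
Title: Multi-Omics Integration of Early-Life Antibiotic Exposure Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dam-pup microbiome cohorts with matched
    lipidomics and transcriptomics. Provides dam-to-pup microbiota
    transfer-fidelity scoring, alpha/beta diversity with PCoA and PERMANOVA,
    a LEfSe-style differential-abundance screen, a from-scratch two-component
    PLS-DA with VIP scores for ratio-plus-VIP lipid screening, lipid shorthand
    nomenclature parsing with cognate lysophosphatidylcholine to fatty-acid
    matching, and assembly of integrated taxa-lipid-gene correlation networks.
    Includes a synthetic multi-omics cohort generator with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    igraph,
    jsonlite,
    yaml,
    tibble,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
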