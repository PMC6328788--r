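Package: PathwayInstability
Title: Pathway Instability Scoring of Somatic Mutation Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the somatic mutation burden of molecular pathways.
    Per-gene mutation rates are normalized by coding-sequence length (nMR)
    and averaged over the members of each gene set to yield a Pathway
    Instability (PI) score per tumor sample. PI and nMR score matrices are
    screened for cancer-type biomarkers with one-vs-rest and pairwise
    Mann-Whitney AUC tests; pairwise biomarker counts serve as a distance
    matrix for Ward.D2 clustering of tumor localizations. Includes readers
    for COSMIC-dialect mutation tables and GMT gene sets, a principal
    component analysis helper, and a seed-deterministic synthetic cohort
    generator with planted pathway enrichments for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
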