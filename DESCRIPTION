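Package: cytoPrior
Title: Prioritization of Candidate Genes and Copy Number Variations from
    Molecular Cytogenetic Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for in silico evaluation of chromosome imbalances and copy
    number variations (CNVs). Genes inside an imbalance are filtered by
    tissue-specific expression (locus-aligned outlier detection with a robust
    z-score and a Tukey fence), ranked by interactome proximity to phenotype
    seed genes, pathway co-membership and simulated pathway perturbation
    (node-removal connectivity impact), and the evidence is fused by a
    weighted rank product. CNVs are then prioritized by the presence of at
    least one prioritized gene, screened against a benign-variant catalog by
    reciprocal overlap, and summarized per cohort (per-patient counts and
    diagnostic yield). A synthetic-data module generates complete studies
    with planted ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, GenePrediction, NetworkInference,
    GeneExpression, Software
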