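Package: scRubric
Title: Transparent Rubric-Based Cell-Type Annotation for scRNA-seq Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A deterministic, auditable engine for annotating scRNA-seq
    clusters with cell types. A three-stage Prospector-Insightor-Reviewer
    pipeline shortlists plausible identities from a user-supplied marker
    knowledge base, scores every candidate against per-cluster evidence
    (one-vs-rest Wilcoxon marker genes, hypergeometric pathway
    over-representation, biological context) with an explicit point rubric,
    and reports exactly three ranked, evidence-backed candidates per
    cluster together with itemized score breakdowns. Annotations are
    evaluated against reference labels with a three-level Cell Ontology
    agreement metric (full / partial / mismatch) aggregated by the maximum
    over a cluster's candidates. A seeded negative-binomial simulator with
    planted marker signatures makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap,
    parallel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
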