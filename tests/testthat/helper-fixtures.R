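# Shared in-code fixtures: a small immune/liver knowledge base, matching
# ontology fragments, and constructors for hand-built evidence bundles.

demoKB <- function() {
  markerKnowledgeBase(
    markerEntry("B cell", clId = "CL:0000236",
                broadMarkers = c("CD19", "MS4A1", "CD79A"),
                narrowMarkers = "TCL1A",
                negativeMarkers = c("CD3D", "CD3E"),
                tissues = "blood",
                states = "activated@blood:inflammation",
                pathwaysType = "B cell receptor signaling",
                pathwaysState = "interferon response",
                synonyms = c("B cells", "B-cell")),
    markerEntry("T cell", clId = "CL:0000084",
                broadMarkers = c("CD3D", "CD3E", "CD2"),
                narrowMarkers = "CD8A",
                negativeMarkers = c("CD19", "MS4A1"),
                tissues = "blood",
                pathwaysType = "T cell receptor signaling",
                synonyms = "T cells"),
    markerEntry("NK cell", clId = "CL:0000623",
                broadMarkers = c("GNLY", "NKG7", "KLRD1"),
                tissues = "blood"),
    markerEntry("monocyte", clId = "CL:0000576",
                broadMarkers = c("CD14", "LYZ", "FCN1"),
                tissues = "blood"),
    markerEntry("hepatocyte", clId = "CL:0000182",
                broadMarkers = c("ALB", "APOA1", "TTR"),
                tissues = "liver"))
}

# Five blood-resident types with disjoint markers: the planted-signature
# recovery fixture (all types plausible under a blood context).
bloodKB5 <- function() {
  markerKnowledgeBase(
    markerEntry("B cell", clId = "CL:0000236",
                broadMarkers = c("CD19", "MS4A1", "CD79A"),
                narrowMarkers = "TCL1A", negativeMarkers = "CD3E",
                tissues = "blood", synonyms = c("B cells", "B-cell")),
    markerEntry("T cell", clId = "CL:0000084",
                broadMarkers = c("CD3D", "CD3E", "CD2"),
                narrowMarkers = "CD8A", negativeMarkers = "CD19",
                tissues = "blood", synonyms = "T cells"),
    markerEntry("NK cell", clId = "CL:0000623",
                broadMarkers = c("GNLY", "NKG7", "KLRD1"),
                negativeMarkers = "CD14", tissues = "blood"),
    markerEntry("monocyte", clId = "CL:0000576",
                broadMarkers = c("CD14", "LYZ", "FCN1"),
                negativeMarkers = "GNLY", tissues = "blood"),
    markerEntry("dendritic cell", clId = "CL:0000451",
                broadMarkers = c("FCER1A", "CST3", "CLEC9A"),
                negativeMarkers = "LYZ", tissues = "blood"))
}

# Lymphocyte/hepatocyte ontology fragment: B, T, NK under lymphocyte;
# CD8 T under T; hepatocyte in a disjoint epithelial branch.
demoOntology <- function(broadCategory = character()) {
  terms <- c("CL:0000000", "CL:0000542", "CL:0000236", "CL:0000084",
             "CL:0000625", "CL:0000623", "CL:0000576", "CL:0000066",
             "CL:0000182", "CL:0000451")
  edges <- data.frame(
    child = c("CL:0000542", "CL:0000236", "CL:0000084", "CL:0000625",
              "CL:0000623", "CL:0000576", "CL:0000066", "CL:0000182",
              "CL:0000451"),
    parent = c("CL:0000000", "CL:0000542", "CL:0000542", "CL:0000084",
               "CL:0000542", "CL:0000000", "CL:0000000", "CL:0000066",
               "CL:0000000"),
    stringsAsFactors = FALSE)
  ontologyGraph(terms, edges, broadCategory = broadCategory)
}

# KB containing both a parent and a child term (for partial-match tests).
tcellKB <- function() {
  markerKnowledgeBase(
    markerEntry("B cell", clId = "CL:0000236",
                broadMarkers = "CD19", synonyms = "B cells"),
    markerEntry("T cell", clId = "CL:0000084",
                broadMarkers = "CD3D", synonyms = "T cells"),
    markerEntry("CD8-positive T cell", clId = "CL:0000625",
                broadMarkers = "CD8A"),
    markerEntry("hepatocyte", clId = "CL:0000182", broadMarkers = "ALB"))
}

# Hand-built evidence: a DEG gene list, optionally with enrichment rows.
makeEvidence <- function(genes, enrichment = NULL,
                         context = biologicalContext(), sigCut = 0.05,
                         clusterId = "C1") {
  clusterEvidence(clusterId, genes, enrichment = enrichment,
                  context = context, sigCut = sigCut)
}

# Enrichment table in which `sig` terms are significant and `ns` are not.
makeEnrichment <- function(sig, ns = character(0)) {
  terms <- c(sig, ns)
  n <- length(terms)
  data.frame(term = terms,
             overlap_count = c(rep(5L, length(sig)), rep(1L, length(ns))),
             set_size = rep(10L, n), query_size = rep(10L, n),
             universe_size = rep(100L, n),
             p_value = c(rep(1e-6, length(sig)), rep(0.9, length(ns))),
             adjusted_p = c(rep(1e-5, length(sig)), rep(0.95, length(ns))),
             stringsAsFactors = FALSE)
}

# Tiny deterministic count matrix: gene g is expressed only in cluster A.
toyCounts <- function() {
  counts <- rbind(
    G1 = c(5L, 7L, 6L, 0L, 0L, 0L),
    G2 = c(2L, 2L, 2L, 2L, 2L, 2L),
    G3 = c(0L, 1L, 0L, 1L, 0L, 1L))
  colnames(counts) <- paste0("cell", 1:6)
  countsWithClusters(counts, c("A", "A", "A", "B", "B", "B"))
}

writeKBTsvFixture <- function(path, rows) {
  header <- paste(c("cell_type", "cl_id", "broad_markers", "narrow_markers",
                    "negative_markers", "tissues", "states", "pathways_type",
                    "pathways_state", "synonyms"), collapse = "\t")
  writeLines(c(header, rows), path)
}
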