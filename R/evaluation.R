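# Map a label to (canonical-or-normalized string, ontology term id).
labelKey <- function(label, kb, ontology) {
  canon <- resolveLabel(label, kb)
  id <- NA_character_
  if (!is.na(canon)) {
    e <- kbEntry(kb, canon)
    if (nzchar(e@clId)) id <- e@clId
    key <- normalizeLabel(canon)
  } else {
    if (label %in% ontology@terms) id <- label
    key <- normalizeLabel(label)
  }
  list(key = key, id = id, resolved = !is.na(canon))
}

#' Three-level agreement between two cell-type labels
#'
#' Full match (1.0) when the canonicalized labels are identical or both
#' map to the same Cell Ontology term; partial match (0.5) when one term
#' is an ancestor or descendant of the other in the is_a hierarchy (any
#' distance) or both map to the same configured broad category; mismatch
#' (0.0) otherwise — two terms sharing only a remote common ancestor
#' (neither on the other's lineage) do not count as related. Symmetric in
#' its arguments. A label that neither resolves in the knowledge base nor
#' is itself an ontology term is compared by canonical string only (a
#' message notes this).
#'
#' @param predicted,reference nonempty cell-type labels.
#' @param kb a [MarkerKnowledgeBase-class] used to canonicalize labels
#'   and look up CL ids.
#' @param ontology an [OntologyGraph-class].
#' @return 1.0, 0.5 or 0.0.
#' @export
agreement <- function(predicted, reference, kb, ontology) {
  if (!nzchar(trimws(predicted)) || !nzchar(trimws(reference)))
    stop("labels must be nonempty")
  a <- labelKey(predicted, kb, ontology)
  b <- labelKey(reference, kb, ontology)
  if (is.na(a$id) && !a$resolved || is.na(b$id) && !b$resolved)
    message("agreement: label without CL id or KB resolution; ",
            "comparing by canonical string only")
  if (identical(a$key, b$key)) return(1.0)
  if (!is.na(a$id) && !is.na(b$id)) {
    if (identical(a$id, b$id)) return(1.0)
    if (a$id %in% ontologyAncestors(ontology, b$id) ||
        b$id %in% ontologyAncestors(ontology, a$id)) return(0.5)
    ca <- ontologyCategory(ontology, a$id)
    cb <- ontologyCategory(ontology, b$id)
    if (!is.na(ca) && !is.na(cb) && identical(ca, cb)) return(0.5)
  }
  0.0
}

#' Cluster-level agreement: max over the three candidates
#'
#' Scores each candidate label against the reference and aggregates by
#' the maximum (the benchmark rule for a tool that reports three
#' candidates per cluster).
#'
#' @param candidates character vector of candidate labels (1-3; NA or ""
#'   entries, e.g. absent report slots, are ignored).
#' @param reference the reference label.
#' @param kb,ontology see [agreement()].
#' @param clusterId optional cluster id carried into the result.
#' @return an [AgreementResult-class].
#' @export
clusterAgreement <- function(candidates, reference, kb, ontology,
                             clusterId = "") {
  candidates <- candidates[!is.na(candidates) & nzchar(candidates)]
  if (!length(candidates)) stop("need at least one candidate label")
  per <- unname(vapply(candidates, agreement, numeric(1),
                       reference = reference, kb = kb,
                       ontology = ontology))
  new("AgreementResult", clusterId = as.character(clusterId),
      perCandidate = per, score = max(per),
      matchedIndex = which.max(per))
}

#' Summarize agreement results over clusters
#'
#' @param results nonempty list of [AgreementResult-class].
#' @return a [BenchmarkSummary-class] with the arithmetic mean of cluster
#'   scores and full/partial/mismatch counts.
#' @export
summarizeAgreement <- function(results) {
  if (!length(results)) stop("no agreement results to summarize")
  scores <- vapply(results, agreementScore, numeric(1))
  counts <- c(full = sum(scores == 1), partial = sum(scores == 0.5),
              mismatch = sum(scores == 0))
  new("BenchmarkSummary", results = results,
      meanAgreement = mean(scores), counts = counts)
}

#' Evaluate an annotation report against reference labels
#'
#' Reads the top-three candidate names per cluster out of the report,
#' scores each cluster against its reference label with
#' [clusterAgreement()] and aggregates with [summarizeAgreement()].
#' Errored clusters (no candidates) score 0.
#'
#' @param report an [AnnotationReport-class].
#' @param reference named character vector (cluster id -> reference
#'   label), or a data.frame with columns cluster_id, reference_label.
#' @param kb,ontology see [agreement()].
#' @return a [BenchmarkSummary-class].
#' @export
evaluateReport <- function(report, reference, kb, ontology) {
  if (is.data.frame(reference))
    reference <- stats::setNames(as.character(reference$reference_label),
                                 as.character(reference$cluster_id))
  results <- list()
  for (rec in reportClusters(report)) {
    cl <- rec$cluster_id
    if (!cl %in% names(reference))
      stop("no reference label for cluster '", cl, "'")
    if (!is.null(rec$error)) {
      results[[cl]] <- new("AgreementResult", clusterId = cl,
                           perCandidate = 0, score = 0,
                           matchedIndex = 1L)
      next
    }
    nms <- vapply(rec$candidates, function(cand)
      if (isTRUE(cand$absent)) NA_character_ else cand$name, character(1))
    results[[cl]] <- clusterAgreement(nms, reference[[cl]], kb, ontology,
                                      clusterId = cl)
  }
  summarizeAgreement(results)
}

#' Read a two-column reference-label TSV
#'
#' @param path TSV with columns cluster_id, reference_label (optional
#'   header, `#` comments tolerated).
#' @return named character vector cluster id -> label.
#' @export
readReferenceLabels <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = "character")
  if (nrow(df) && normalizeLabel(df[1, 1]) %in% c("cluster id", "cluster"))
    df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
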