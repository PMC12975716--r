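#' BiologicalContext: tissue / condition / species descriptor
#'
#' Carries the experimental context that steers annotation: tissue source,
#' disease state or experimental condition, species, and free-text notes.
#' An empty tissue means "unrestricted" — every cell type is considered
#' plausible and no implausibility deduction is ever applied.
#'
#' @slot tissue character(1); may be "" for unrestricted.
#' @slot condition character(1) disease state or experimental condition.
#' @slot species character(1).
#' @slot notes character(1) free text.
#' @export
setClass("BiologicalContext",
  representation(tissue = "character", condition = "character",
                 species = "character", notes = "character"),
  prototype(tissue = "", condition = "", species = "", notes = ""))

#' Construct a BiologicalContext
#'
#' @param tissue tissue label ("" = unrestricted).
#' @param condition disease state / experimental condition.
#' @param species species label.
#' @param notes free text.
#' @return a [BiologicalContext-class] object.
#' @examples
#' biologicalContext(tissue = "blood", species = "human")
#' @export
biologicalContext <- function(tissue = "", condition = "", species = "",
                              notes = "") {
  new("BiologicalContext", tissue = as.character(tissue),
      condition = as.character(condition), species = as.character(species),
      notes = as.character(notes))
}

setMethod("show", "BiologicalContext", function(object) {
  cat("BiologicalContext: tissue=",
      if (nzchar(object@tissue)) object@tissue else "<unrestricted>",
      ", condition=", ifelse(nzchar(object@condition), object@condition, "-"),
      ", species=", ifelse(nzchar(object@species), object@species, "-"),
      "\n", sep = "")
})

#' MarkerEntry: prior knowledge about one cell type
#'
#' One knowledge-base record: the canonical label, optional Cell Ontology
#' id, the three marker sets the rubric scores against (broad, narrow
#' high-specificity, and negative markers — genes that should *not* be
#' expressed), the tissues and states where the type is plausible, its
#' characteristic pathway terms (tagged type vs state), and accepted
#' synonyms. Broad, narrow and negative marker sets must be pairwise
#' disjoint.
#'
#' @slot cellType canonical label (nonempty).
#' @slot clId Cell Ontology term id or "".
#' @slot broadMarkers,narrowMarkers,negativeMarkers upper-cased gene symbols.
#' @slot tissues tissue labels where the type is plausible (empty =
#'   plausible anywhere).
#' @slot states plausible state tags, `"label"`, `"label@tissue"` or
#'   `"label@tissue:condition"` (empty tag parts match anything).
#' @slot pathwaysType,pathwaysState characteristic pathway-term strings.
#' @slot synonyms alternative labels.
#' @export
setClass("MarkerEntry",
  representation(cellType = "character", clId = "character",
                 broadMarkers = "character", narrowMarkers = "character",
                 negativeMarkers = "character", tissues = "character",
                 states = "character", pathwaysType = "character",
                 pathwaysState = "character", synonyms = "character"),
  validity = function(object) {
    if (length(object@cellType) != 1L || !nzchar(trimws(object@cellType)))
      return("cellType must be a nonempty string")
    pairs <- list(c("broadMarkers", "narrowMarkers"),
                  c("broadMarkers", "negativeMarkers"),
                  c("narrowMarkers", "negativeMarkers"))
    for (p in pairs) {
      both <- intersect(slot(object, p[1]), slot(object, p[2]))
      if (length(both))
        return(sprintf("entry '%s': gene(s) %s listed in both %s and %s",
                       object@cellType, paste(both, collapse = ","),
                       p[1], p[2]))
    }
    TRUE
  })

#' Construct a MarkerEntry
#'
#' Gene symbols are upper-cased and de-duplicated; all sets are stored in a
#' deterministic (byte) order.
#'
#' @param cellType canonical label.
#' @param clId optional Cell Ontology id.
#' @param broadMarkers,narrowMarkers,negativeMarkers gene symbols.
#' @param tissues,states,pathwaysType,pathwaysState,synonyms see
#'   [MarkerEntry-class].
#' @return a [MarkerEntry-class] object.
#' @examples
#' markerEntry("B cell", clId = "CL:0000236",
#'             broadMarkers = c("CD19", "MS4A1"), tissues = "blood")
#' @export
markerEntry <- function(cellType, clId = "", broadMarkers = character(),
                        narrowMarkers = character(),
                        negativeMarkers = character(),
                        tissues = character(), states = character(),
                        pathwaysType = character(),
                        pathwaysState = character(),
                        synonyms = character()) {
  clean <- function(x) sortC(unique(trimws(x[nzchar(trimws(x))])))
  new("MarkerEntry",
      cellType = trimws(cellType), clId = as.character(clId),
      broadMarkers = sortC(unique(normalizeGenes(broadMarkers))),
      narrowMarkers = sortC(unique(normalizeGenes(narrowMarkers))),
      negativeMarkers = sortC(unique(normalizeGenes(negativeMarkers))),
      tissues = clean(tissues), states = clean(states),
      pathwaysType = clean(pathwaysType), pathwaysState = clean(pathwaysState),
      synonyms = clean(synonyms))
}

setMethod("show", "MarkerEntry", function(object) {
  cat("MarkerEntry '", object@cellType, "'",
      if (nzchar(object@clId)) paste0(" [", object@clId, "]"), "\n",
      "  broad: ", paste(object@broadMarkers, collapse = ", "), "\n",
      "  narrow: ", paste(object@narrowMarkers, collapse = ", "), "\n",
      "  negative: ", paste(object@negativeMarkers, collapse = ", "), "\n",
      "  tissues: ", paste(object@tissues, collapse = ", "), "\n", sep = "")
})

#' MarkerKnowledgeBase: the collection of MarkerEntry records
#'
#' Entries are keyed by canonical name; lookup by any synonym resolves to
#' exactly one entry (synonym collisions across entries are rejected at
#' construction).
#'
#' @slot entries named list of [MarkerEntry-class] objects.
#' @export
setClass("MarkerKnowledgeBase",
  representation(entries = "list"),
  validity = function(object) {
    if (length(object@entries) == 0L) return(TRUE)
    if (!all(vapply(object@entries, is, logical(1), "MarkerEntry")))
      return("entries must all be MarkerEntry objects")
    nm <- vapply(object@entries, function(e) e@cellType, character(1))
    if (!identical(unname(names(object@entries)), unname(nm)))
      return("entry list names must equal the entries' canonical cellType")
    if (anyDuplicated(normalizeLabel(nm)))
      return(sprintf("duplicate canonical cell type name(s): %s",
                     paste(nm[duplicated(normalizeLabel(nm))],
                           collapse = ", ")))
    # any alias (synonym or canonical name) must resolve to a single entry
    alias <- data.frame(
      key = unlist(lapply(object@entries,
                          function(e) normalizeLabel(c(e@cellType,
                                                       e@synonyms)))),
      entry = rep(nm, vapply(object@entries,
                             function(e) length(e@synonyms) + 1L,
                             integer(1))),
      stringsAsFactors = FALSE)
    alias <- unique(alias)
    bad <- alias$key[duplicated(alias$key)]
    if (length(bad))
      return(sprintf("synonym collision across entries: '%s'", bad[1]))
    TRUE
  })

#' Construct a MarkerKnowledgeBase from MarkerEntry objects
#'
#' @param entries a list of [MarkerEntry-class] objects (or several entries
#'   given as `...`).
#' @param ... additional entries.
#' @return a [MarkerKnowledgeBase-class].
#' @export
markerKnowledgeBase <- function(entries = list(), ...) {
  if (is(entries, "MarkerEntry")) entries <- list(entries)
  entries <- c(entries, list(...))
  nm <- vapply(entries, function(e) e@cellType, character(1))
  entries <- entries[orderC(nm)]
  names(entries) <- vapply(entries, function(e) e@cellType, character(1))
  new("MarkerKnowledgeBase", entries = entries)
}

setMethod("show", "MarkerKnowledgeBase", function(object) {
  cat("MarkerKnowledgeBase with", length(object@entries), "cell type(s):",
      paste(head(names(object@entries), 8), collapse = ", "),
      if (length(object@entries) > 8) "...", "\n")
})

setMethod("length", "MarkerKnowledgeBase",
          function(x) length(x@entries))

#' Accessors for MarkerKnowledgeBase and MarkerEntry
#'
#' `kbNames()` returns the canonical cell-type names; `kbEntry()` fetches
#' one entry by canonical name; `cellType()`, `clId()`, `broadMarkers()`,
#' `narrowMarkers()` and `negativeMarkers()` read MarkerEntry slots.
#'
#' @param kb a [MarkerKnowledgeBase-class].
#' @param name canonical cell-type name.
#' @param x a [MarkerEntry-class].
#' @return character vector(s) as described.
#' @export
kbNames <- function(kb) names(kb@entries)

#' @rdname kbNames
#' @export
kbEntry <- function(kb, name) {
  if (!name %in% names(kb@entries))
    stop("no knowledge-base entry named '", name, "'")
  kb@entries[[name]]
}

#' @rdname kbNames
#' @export
cellType <- function(x) x@cellType

#' @rdname kbNames
#' @export
clId <- function(x) x@clId

#' @rdname kbNames
#' @export
broadMarkers <- function(x) x@broadMarkers

#' @rdname kbNames
#' @export
narrowMarkers <- function(x) x@narrowMarkers

#' @rdname kbNames
#' @export
negativeMarkers <- function(x) x@negativeMarkers

#' OntologyGraph: a directed acyclic is_a hierarchy of cell-type terms
#'
#' Terms with optional names, child-to-parent `is_a` edges, and an optional
#' term-to-broad-category map used for partial matching in the agreement
#' metric. Construction validates that every edge endpoint is declared and
#' that the graph is acyclic.
#'
#' @slot terms character vector of term ids.
#' @slot termNames named character, id -> display name.
#' @slot parents named list, id -> character vector of parent ids.
#' @slot broadCategory named character, id -> category label (may be empty).
#' @export
setClass("OntologyGraph",
  representation(terms = "character", termNames = "character",
                 parents = "list", broadCategory = "character"),
  prototype(terms = character(), termNames = character(),
            parents = list(), broadCategory = character()))

#' Construct an OntologyGraph
#'
#' @param terms character vector of term ids (endpoints of `edges` are
#'   implicitly allowed only if listed here).
#' @param edges data.frame with columns `child`, `parent` (is_a edges).
#' @param termNames optional named character of display names.
#' @param broadCategory optional named character, term id -> category.
#' @return an [OntologyGraph-class].
#' @examples
#' ontologyGraph(c("CL:a", "CL:b"),
#'               data.frame(child = "CL:b", parent = "CL:a"))
#' @export
ontologyGraph <- function(terms, edges = NULL, termNames = character(),
                          broadCategory = character()) {
  terms <- unique(as.character(terms))
  parents <- stats::setNames(rep(list(character(0)), length(terms)), terms)
  if (!is.null(edges) && nrow(edges)) {
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    undeclared <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(undeclared))
      stop("ontology edge references undeclared term(s): ",
           paste(undeclared, collapse = ", "))
    for (i in seq_len(nrow(edges)))
      parents[[edges$child[i]]] <-
        sortC(unique(c(parents[[edges$child[i]]], edges$parent[i])))
  }
  g <- new("OntologyGraph", terms = sortC(terms),
           termNames = termNames, parents = parents,
           broadCategory = broadCategory)
  cyc <- findCycle(g)
  if (!is.null(cyc))
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  g
}

setMethod("show", "OntologyGraph", function(object) {
  nEdges <- sum(lengths(object@parents))
  cat("OntologyGraph:", length(object@terms), "terms,", nEdges,
      "is_a edge(s)\n")
})

#' RubricConfig: the point rubric for candidate scoring
#'
#' Default values are the standard three-component rubric: proportional
#' credit up to each positive maximum, fixed one-shot deductions for
#' contradicting signals.
#'
#' @slot markerMatchMax +45, broad marker matches (max).
#' @slot narrowMarkerMax +15, narrow high-specificity matches (max).
#' @slot sharedMarkerDeduction -10, marker shared with another candidate.
#' @slot negativeMarkerDeduction -30, negative marker present.
#' @slot pathwayStateMax +15, enriched pathways fit the cell state (max).
#' @slot pathwayTypeMax +5, enriched pathways fit the cell type (max).
#' @slot pathwaySharedDeduction -10, pathway also enriched in another
#'   candidate.
#' @slot pathwayConflictDeduction -20, conflicting pathways.
#' @slot contextTypeMax +10, cell type plausible in tissue/condition (max).
#' @slot contextStateMax +10, cell state plausible in tissue/condition (max).
#' @slot contextImplausibleDeduction -30, biologically implausible.
#' @export
setClass("RubricConfig",
  representation(markerMatchMax = "numeric", narrowMarkerMax = "numeric",
                 sharedMarkerDeduction = "numeric",
                 negativeMarkerDeduction = "numeric",
                 pathwayStateMax = "numeric", pathwayTypeMax = "numeric",
                 pathwaySharedDeduction = "numeric",
                 pathwayConflictDeduction = "numeric",
                 contextTypeMax = "numeric", contextStateMax = "numeric",
                 contextImplausibleDeduction = "numeric"),
  prototype(markerMatchMax = 45, narrowMarkerMax = 15,
            sharedMarkerDeduction = -10, negativeMarkerDeduction = -30,
            pathwayStateMax = 15, pathwayTypeMax = 5,
            pathwaySharedDeduction = -10, pathwayConflictDeduction = -20,
            contextTypeMax = 10, contextStateMax = 10,
            contextImplausibleDeduction = -30),
  validity = function(object) {
    maxima <- c(object@markerMatchMax, object@narrowMarkerMax,
                object@pathwayStateMax, object@pathwayTypeMax,
                object@contextTypeMax, object@contextStateMax)
    ded <- c(object@sharedMarkerDeduction, object@negativeMarkerDeduction,
             object@pathwaySharedDeduction, object@pathwayConflictDeduction,
             object@contextImplausibleDeduction)
    if (any(maxima < 0)) return("maxima must be >= 0")
    if (any(ded > 0)) return("deductions must be <= 0")
    TRUE
  })

#' Construct a RubricConfig (standard defaults)
#'
#' @param ... named overrides of any [RubricConfig-class] slot.
#' @return a [RubricConfig-class].
#' @examples
#' rubricConfig()                      # standard defaults
#' rubricConfig(markerMatchMax = 50)   # custom scheme
#' @export
rubricConfig <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), slotNames("RubricConfig"))
  if (length(bad))
    stop("unknown rubric field(s): ", paste(bad, collapse = ", "))
  do.call(new, c(list(Class = "RubricConfig"), args))
}

setMethod("show", "RubricConfig", function(object) {
  cat("RubricConfig (points):\n")
  for (s in slotNames(object))
    cat(sprintf("  %-28s %+g\n", s, slot(object, s)))
})

rubricToList <- function(config) {
  out <- lapply(slotNames("RubricConfig"),
                function(s) as.numeric(slot(config, s)))
  names(out) <- slotNames("RubricConfig")
  out
}

#' ClusterEvidence: the data-driven evidence bundle for one cluster
#'
#' Ranked marker genes (one-vs-rest Wilcoxon DEGs), optional pathway
#' over-representation results for those markers, and the shared
#' biological context.
#'
#' @slot clusterId character(1).
#' @slot markers data.frame with columns gene, log2_fold_change, p_value,
#'   adjusted_p, rank.
#' @slot enrichment data.frame of enrichment results, or NULL when no
#'   gene-set collection was supplied (triggers two-component scoring).
#' @slot context a [BiologicalContext-class].
#' @slot sigCut adjusted-p threshold below which an enriched term counts as
#'   significant for scoring.
#' @export
setClass("ClusterEvidence",
  representation(clusterId = "character", markers = "data.frame",
                 enrichment = "ANY", context = "BiologicalContext",
                 sigCut = "numeric"),
  prototype(enrichment = NULL, sigCut = 0.05),
  validity = function(object) {
    need <- c("gene", "log2_fold_change", "p_value", "adjusted_p", "rank")
    if (!all(need %in% names(object@markers)))
      return(paste("markers data.frame must have columns:",
                   paste(need, collapse = ", ")))
    if (!is.null(object@enrichment) && !is.data.frame(object@enrichment))
      return("enrichment must be NULL or a data.frame")
    TRUE
  })

#' Construct a ClusterEvidence bundle
#'
#' Usually produced by [extractEvidence()]; the constructor is exported so
#' evidence can also be assembled by hand (e.g. for audits of the rubric).
#'
#' @param clusterId cluster identifier.
#' @param markers data.frame of ranked markers (see
#'   [ClusterEvidence-class]); a bare character vector of gene symbols is
#'   also accepted and wrapped with rank-order metadata.
#' @param enrichment data.frame of enrichment results or NULL.
#' @param context a [BiologicalContext-class].
#' @param sigCut significance cut for enriched terms (default 0.05).
#' @return a [ClusterEvidence-class].
#' @export
clusterEvidence <- function(clusterId, markers,
                            enrichment = NULL,
                            context = biologicalContext(),
                            sigCut = 0.05) {
  if (is.character(markers)) {
    genes <- normalizeGenes(markers)
    markers <- data.frame(gene = genes,
                          log2_fold_change = rep(NA_real_, length(genes)),
                          p_value = rep(NA_real_, length(genes)),
                          adjusted_p = rep(NA_real_, length(genes)),
                          rank = seq_along(genes),
                          stringsAsFactors = FALSE)
  }
  new("ClusterEvidence", clusterId = as.character(clusterId),
      markers = markers, enrichment = enrichment, context = context,
      sigCut = sigCut)
}

setMethod("show", "ClusterEvidence", function(object) {
  cat("ClusterEvidence for cluster '", object@clusterId, "': ",
      nrow(object@markers), " ranked genes, ",
      if (is.null(object@enrichment)) "no enrichment"
      else paste0(nrow(object@enrichment), " enrichment terms"),
      "\n", sep = "")
})

#' Top marker genes of a ClusterEvidence bundle
#' @param evidence a [ClusterEvidence-class].
#' @return character vector of gene symbols in rank order.
#' @export
topGenes <- function(evidence) as.character(evidence@markers$gene)

#' ScoreBreakdown: itemized rubric points for one candidate
#'
#' The transparency artifact: one field per rubric criterion with the
#' evidence items that triggered it, per-component subtotals, and the
#' grand total (which always equals the sum of the criterion points).
#' `pathwayComponent` has length 0 when the two-component path (no
#' enrichment data) was used.
#'
#' @slot candidate candidate cell-type name.
#' @slot criteria named numeric of criterion points.
#' @slot items named list of character vectors: the evidence items behind
#'   each criterion.
#' @slot markerComponent,contextComponent numeric(1) subtotals.
#' @slot pathwayComponent numeric(1) subtotal, or numeric(0) when pathway
#'   scoring was skipped.
#' @slot total numeric(1).
#' @export
setClass("ScoreBreakdown",
  representation(candidate = "character", criteria = "numeric",
                 items = "list", markerComponent = "numeric",
                 pathwayComponent = "numeric", contextComponent = "numeric",
                 total = "numeric"),
  validity = function(object) {
    if (abs(object@total - sum(object@criteria)) > 1e-9)
      return("total must equal the sum of criterion points")
    comp <- object@markerComponent + object@contextComponent +
      (if (length(object@pathwayComponent)) object@pathwayComponent else 0)
    if (abs(object@total - comp) > 1e-9)
      return("total must equal the sum of the components")
    TRUE
  })

setMethod("show", "ScoreBreakdown", function(object) {
  cat("ScoreBreakdown for '", object@candidate, "': total ", object@total,
      "\n", sep = "")
  nz <- object@criteria[object@criteria != 0]
  for (i in seq_along(nz))
    cat(sprintf("  %-28s %+g  [%s]\n", names(nz)[i], nz[i],
                paste(object@items[[names(nz)[i]]], collapse = ", ")))
})

#' Total points of a ScoreBreakdown
#' @param breakdown a [ScoreBreakdown-class].
#' @return numeric(1).
#' @export
breakdownTotal <- function(breakdown) breakdown@total

#' CandidateShortlist: the Prospector's plausible cell types
#'
#' Ordered canonical names drawn from the knowledge base, each with a
#' provenance note saying why it was shortlisted.
#'
#' @slot names character vector of canonical cell-type names (no
#'   duplicates).
#' @slot provenance named character, name -> reason.
#' @export
setClass("CandidateShortlist",
  representation(names = "character", provenance = "character"),
  validity = function(object) {
    if (anyDuplicated(object@names)) return("shortlist names must be unique")
    TRUE
  })

setMethod("show", "CandidateShortlist", function(object) {
  cat("CandidateShortlist (", length(object@names), "): ",
      paste(object@names, collapse = ", "), "\n", sep = "")
})

#' @describeIn kbNames names on a CandidateShortlist
#' @param shortlist a [CandidateShortlist-class].
#' @export
shortlistNames <- function(shortlist) shortlist@names

#' AnnotationBackend: pluggable candidate-scoring engine
#'
#' The contract every reasoning backend fulfils: given the shortlisted
#' knowledge-base entries and one cluster's evidence, return one
#' [ScoreBreakdown-class] per candidate. The reference backend
#' ([rubricBackend()]) is the deterministic rubric engine; a replay
#' backend ([replayBackend()]) answers only from a recorded fixture and
#' fails loudly on a cache miss. A backend flagged `deterministic` must be
#' bit-for-bit reproducible.
#'
#' @slot name identity label.
#' @slot deterministic logical(1).
#' @slot scoreFun function(entries, evidence, context, config) -> list of
#'   ScoreBreakdown.
#' @export
setClass("AnnotationBackend",
  representation(name = "character", deterministic = "logical",
                 scoreFun = "function"))

setMethod("show", "AnnotationBackend", function(object) {
  cat("AnnotationBackend '", object@name, "' (deterministic: ",
      object@deterministic, ")\n", sep = "")
})

#' AnnotationReport: the audit-ready result of a full run
#'
#' Run metadata (config hash, seed, backend identity, timestamp) plus one
#' record per cluster. Every non-errored cluster record carries exactly
#' three candidate slots (absent slots are marked explicitly when the
#' knowledge base is too small); every reported number is traceable to a
#' ScoreBreakdown field embedded in the record.
#'
#' @slot metadata list of run metadata.
#' @slot clusters named list of per-cluster records (plain lists, so the
#'   report round-trips losslessly through JSON).
#' @export
setClass("AnnotationReport",
  representation(metadata = "list", clusters = "list"),
  validity = function(object) {
    for (rec in object@clusters) {
      if (!is.null(rec$error)) next
      if (length(rec$candidates) != 3L)
        return(sprintf("cluster '%s' must carry exactly 3 candidate slots",
                       rec$cluster_id))
    }
    TRUE
  })

setMethod("show", "AnnotationReport", function(object) {
  cat("AnnotationReport: ", length(object@clusters),
      " cluster(s), backend '", object@metadata$backend, "'\n", sep = "")
  for (rec in object@clusters) {
    if (!is.null(rec$error)) {
      cat("  ", rec$cluster_id, ": ERROR (", rec$error, ")\n", sep = "")
    } else {
      top <- rec$candidates[[1]]
      cat("  ", rec$cluster_id, ": ", top$name, " (", top$breakdown$total,
          if (isTRUE(rec$flagged)) ", low-agreement flag", ")\n", sep = "")
    }
  }
})

#' Per-cluster records of an AnnotationReport
#' @param report an [AnnotationReport-class].
#' @return named list of cluster records.
#' @export
reportClusters <- function(report) report@clusters

#' Run metadata of an AnnotationReport
#' @param report an [AnnotationReport-class].
#' @return list of metadata fields.
#' @export
reportMetadata <- function(report) report@metadata

#' AgreementResult: three-level agreement for one cluster
#'
#' Per-candidate agreement scores in \{0, 0.5, 1\} against the reference
#' label, aggregated by the maximum over the cluster's candidates.
#'
#' @slot clusterId character(1).
#' @slot perCandidate numeric vector of per-candidate scores.
#' @slot score numeric(1), the maximum.
#' @slot matchedIndex integer(1) index of the first candidate attaining
#'   the maximum.
#' @export
setClass("AgreementResult",
  representation(clusterId = "character", perCandidate = "numeric",
                 score = "numeric", matchedIndex = "integer"),
  validity = function(object) {
    lv <- c(0, 0.5, 1)
    if (!all(object@perCandidate %in% lv))
      return("per-candidate agreement must be one of 0, 0.5, 1")
    if (!isTRUE(all.equal(object@score, max(object@perCandidate))))
      return("cluster score must be the max over candidates")
    TRUE
  })

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult '", object@clusterId, "': ", object@score,
      " (per candidate: ", paste(object@perCandidate, collapse = ", "),
      ")\n", sep = "")
})

#' Cluster-level agreement score
#' @param x an [AgreementResult-class].
#' @return numeric(1) in \{0, 0.5, 1\}.
#' @export
agreementScore <- function(x) x@score

#' BenchmarkSummary: aggregate agreement over clusters
#'
#' @slot results list of [AgreementResult-class].
#' @slot meanAgreement numeric(1) arithmetic mean of cluster scores.
#' @slot counts named numeric: full / partial / mismatch tallies.
#' @export
setClass("BenchmarkSummary",
  representation(results = "list", meanAgreement = "numeric",
                 counts = "numeric"),
  validity = function(object) {
    if (object@meanAgreement < 0 || object@meanAgreement > 1)
      return("mean agreement must lie in [0, 1]")
    if (sum(object@counts) != length(object@results))
      return("level counts must sum to the number of clusters")
    TRUE
  })

setMethod("show", "BenchmarkSummary", function(object) {
  cat(sprintf(
    "BenchmarkSummary: mean agreement %.3f over %d cluster(s) (full %d, partial %d, mismatch %d)\n",
    object@meanAgreement, length(object@results),
    object@counts["full"], object@counts["partial"],
    object@counts["mismatch"]))
})

#' Mean agreement of a BenchmarkSummary
#' @param x a [BenchmarkSummary-class].
#' @return numeric(1).
#' @export
meanAgreement <- function(x) x@meanAgreement

#' SynthSpec: parameters for the planted-signature count simulator
#'
#' One cluster is generated per knowledge-base entry. Counts are negative
#' binomial with a common baseline mean and dispersion (size); each
#' planted type's positive markers have their mean multiplied by
#' `markerFold` in its own cluster and its negative markers multiplied by
#' `negativeSuppression`.
#'
#' @slot kb the [MarkerKnowledgeBase-class] of types to plant.
#' @slot cellsPerCluster integer > 0.
#' @slot nBackgroundGenes integer >= 0 extra genes named GBG0001...
#' @slot baselineMean NB mean > 0.
#' @slot dispersion NB size parameter > 0.
#' @slot markerFold multiplicative over-expression, > 1.
#' @slot negativeSuppression factor in (0, 1].
#' @slot seed integer RNG seed.
#' @export
setClass("SynthSpec",
  representation(kb = "MarkerKnowledgeBase", cellsPerCluster = "numeric",
                 nBackgroundGenes = "numeric", baselineMean = "numeric",
                 dispersion = "numeric", markerFold = "numeric",
                 negativeSuppression = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@cellsPerCluster < 1) return("cellsPerCluster must be >= 1")
    if (object@nBackgroundGenes < 0) return("nBackgroundGenes must be >= 0")
    if (object@baselineMean <= 0) return("baselineMean must be > 0")
    if (object@dispersion <= 0) return("dispersion must be > 0")
    if (object@markerFold <= 1) return("markerFold must be > 1")
    if (object@negativeSuppression <= 0 || object@negativeSuppression > 1)
      return("negativeSuppression must lie in (0, 1]")
    if (length(object@kb@entries) == 0L)
      return("the knowledge base to plant must be nonempty")
    TRUE
  })

#' Construct a SynthSpec
#'
#' Defaults describe a small but realistic desk-scale experiment: 50 cells
#' per cluster, 100 background genes, shallow NB counts (mean 2, size 2),
#' eight-fold marker over-expression, ten-fold negative-marker
#' suppression.
#'
#' @param kb knowledge base whose entries are planted (one cluster each);
#'   every entry must have nonempty broad markers.
#' @param cellsPerCluster,nBackgroundGenes,baselineMean,dispersion
#'   simulator parameters, see [SynthSpec-class].
#' @param markerFold,negativeSuppression,seed simulator parameters.
#' @return a [SynthSpec-class].
#' @export
synthSpec <- function(kb, cellsPerCluster = 50, nBackgroundGenes = 100,
                      baselineMean = 2, dispersion = 2, markerFold = 8,
                      negativeSuppression = 0.1, seed = 1) {
  noBroad <- vapply(kb@entries, function(e) length(e@broadMarkers) == 0L,
                    logical(1))
  if (any(noBroad))
    stop("every planted entry needs nonempty broad markers; missing for: ",
         paste(names(kb@entries)[noBroad], collapse = ", "))
  new("SynthSpec", kb = kb, cellsPerCluster = cellsPerCluster,
      nBackgroundGenes = nBackgroundGenes, baselineMean = baselineMean,
      dispersion = dispersion, markerFold = markerFold,
      negativeSuppression = negativeSuppression, seed = seed)
}

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec:", length(object@kb@entries), "planted type(s),",
      object@cellsPerCluster, "cells/cluster, fold",
      object@markerFold, ", seed", object@seed, "\n")
})
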