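# Parse a plausible-state tag "label", "label@tissue" or
# "label@tissue:condition" into its three parts (empty part = wildcard).
parseStateTag <- function(tag) {
  parts <- strsplit(tag, "@", fixed = TRUE)[[1]]
  label <- trimws(parts[1])
  tissue <- ""; condition <- ""
  if (length(parts) > 1L) {
    tc <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
    tissue <- trimws(tc[1])
    if (length(tc) > 1L) condition <- trimws(tc[2])
  }
  list(label = label, tissue = tissue, condition = condition)
}

positiveMarkers <- function(entry) union(entry@broadMarkers,
                                         entry@narrowMarkers)

characteristicPathways <- function(entry) union(entry@pathwaysType,
                                                entry@pathwaysState)

# Proportional credit: cap * matched/total, rounded half-up; 0 when the
# reference set is empty.
proportionalPoints <- function(cap, matched, total) {
  if (total == 0L) return(0)
  roundHalfUp(cap * matched / total)
}

#' Score the marker-profile component of the rubric
#'
#' Awards proportional credit (rounded half-up, capped at the configured
#' maxima) for broad and narrow markers found among the cluster's top
#' DEGs, a single fixed deduction when a matched marker is also a
#' positive marker of another shortlisted candidate (ambiguity), and a
#' single fixed deduction when any of the candidate's negative markers —
#' genes the type should not express — appears among the top DEGs.
#'
#' @param evidence a [ClusterEvidence-class].
#' @param entry the candidate's [MarkerEntry-class].
#' @param shortlist list of the *other* shortlisted [MarkerEntry-class]
#'   objects (competitors).
#' @param config a [RubricConfig-class].
#' @return list with `points` (named numeric: marker_match, narrow_marker,
#'   shared_marker, negative_marker) and `items` (the triggering genes per
#'   criterion).
#' @export
scoreMarkerProfile <- function(evidence, entry, shortlist = list(),
                               config = rubricConfig()) {
  top <- topGenes(evidence)
  matchedBroad <- intersect(entry@broadMarkers, top)
  matchedNarrow <- intersect(entry@narrowMarkers, top)
  matchedPos <- union(matchedBroad, matchedNarrow)
  competitorPos <- unique(unlist(lapply(shortlist, positiveMarkers)))
  shared <- intersect(matchedPos, competitorPos)
  negPresent <- intersect(entry@negativeMarkers, top)
  points <- c(
    marker_match = proportionalPoints(config@markerMatchMax,
                                      length(matchedBroad),
                                      length(entry@broadMarkers)),
    narrow_marker = proportionalPoints(config@narrowMarkerMax,
                                       length(matchedNarrow),
                                       length(entry@narrowMarkers)),
    shared_marker = if (length(shared)) config@sharedMarkerDeduction else 0,
    negative_marker = if (length(negPresent))
      config@negativeMarkerDeduction else 0)
  list(points = points,
       items = list(marker_match = sortC(matchedBroad),
                    narrow_marker = sortC(matchedNarrow),
                    shared_marker = sortC(shared),
                    negative_marker = sortC(negPresent)))
}

#' Score the pathway-profile component of the rubric
#'
#' Operates on the significantly enriched terms (adjusted p below the
#' evidence's `sigCut`). Proportional credit for the candidate's
#' characteristic state and type pathways found enriched; one fixed
#' deduction when a matched pathway is also characteristic of a
#' competitor (specificity loss); one fixed deduction when a significant
#' term is characteristic of a competitor but *not* of this candidate
#' (functional conflict). Returns NULL when the evidence carries no
#' enrichment results — the caller then uses the two-component rubric.
#'
#' @inheritParams scoreMarkerProfile
#' @return list with `points` (pathway_state, pathway_type,
#'   pathway_shared, pathway_conflict) and `items`, or NULL when
#'   enrichment is unavailable.
#' @export
scorePathwayProfile <- function(evidence, entry, shortlist = list(),
                                config = rubricConfig()) {
  if (is.null(evidence@enrichment)) return(NULL)
  enr <- evidence@enrichment
  sig <- as.character(enr$term[enr$adjusted_p < evidence@sigCut])
  matchedState <- intersect(entry@pathwaysState, sig)
  matchedType <- intersect(entry@pathwaysType, sig)
  matched <- union(matchedState, matchedType)
  competitorTerms <- unique(unlist(lapply(shortlist,
                                          characteristicPathways)))
  shared <- intersect(matched, competitorTerms)
  conflict <- intersect(setdiff(sig, characteristicPathways(entry)),
                        competitorTerms)
  points <- c(
    pathway_state = proportionalPoints(config@pathwayStateMax,
                                       length(matchedState),
                                       length(entry@pathwaysState)),
    pathway_type = proportionalPoints(config@pathwayTypeMax,
                                      length(matchedType),
                                      length(entry@pathwaysType)),
    pathway_shared = if (length(shared))
      config@pathwaySharedDeduction else 0,
    pathway_conflict = if (length(conflict))
      config@pathwayConflictDeduction else 0)
  list(points = points,
       items = list(pathway_state = sortC(matchedState),
                    pathway_type = sortC(matchedType),
                    pathway_shared = sortC(shared),
                    pathway_conflict = sortC(conflict)))
}

# A plausible-state tag is compatible with a context when each nonempty
# tag part matches the corresponding nonempty context field.
stateCompatible <- function(tag, context) {
  st <- parseStateTag(tag)
  tOK <- !nzchar(st$tissue) || !nzchar(context@tissue) ||
    normalizeLabel(st$tissue) == normalizeLabel(context@tissue)
  cOK <- !nzchar(st$condition) || !nzchar(context@condition) ||
    normalizeLabel(st$condition) == normalizeLabel(context@condition)
  tOK && cOK
}

#' Score the biological-context component of the rubric
#'
#' Type plausibility points are awarded when the context tissue is empty
#' (unrestricted — absence of context never punishes a candidate), when
#' the entry lists no tissues (plausible anywhere), or when the tissue is
#' among the entry's plausible tissues; otherwise the implausibility
#' deduction applies. State plausibility points are awarded only when the
#' context actually constrains (nonempty tissue or condition) and the
#' entry lists a compatible plausible state.
#'
#' @param entry the candidate's [MarkerEntry-class].
#' @param context a [BiologicalContext-class].
#' @param config a [RubricConfig-class].
#' @return list with `points` (context_type, context_state,
#'   context_implausible) and `items`.
#' @export
scoreContext <- function(entry, context = biologicalContext(),
                         config = rubricConfig()) {
  tissue <- context@tissue
  plausible <- !nzchar(tissue) || length(entry@tissues) == 0L ||
    normalizeLabel(tissue) %in% normalizeLabel(entry@tissues)
  constrained <- nzchar(tissue) || nzchar(context@condition)
  stateHits <- if (constrained)
    entry@states[vapply(entry@states, stateCompatible, logical(1),
                        context = context)]
  else character(0)
  points <- c(
    context_type = if (plausible) config@contextTypeMax else 0,
    context_state = if (length(stateHits)) config@contextStateMax else 0,
    context_implausible = if (!plausible)
      config@contextImplausibleDeduction else 0)
  list(points = points,
       items = list(context_type = if (plausible && nzchar(tissue))
                      tissue else character(0),
                    context_state = sortC(stateHits),
                    context_implausible = if (!plausible)
                      tissue else character(0)))
}

#' Score one candidate against a cluster's evidence
#'
#' Combines the marker, pathway, and context components into an itemized
#' [ScoreBreakdown-class]. When the evidence carries no enrichment
#' results the pathway component is skipped entirely (the two-component
#' rubric: markers + context only) and `pathwayComponent` has length 0.
#' Scoring is a pure function of its inputs.
#'
#' @inheritParams scoreMarkerProfile
#' @param context a [BiologicalContext-class]; defaults to the context
#'   bundled in the evidence.
#' @return a [ScoreBreakdown-class].
#' @export
scoreCandidate <- function(evidence, entry, shortlist = list(),
                           context = evidence@context,
                           config = rubricConfig()) {
  mk <- scoreMarkerProfile(evidence, entry, shortlist, config)
  pw <- scorePathwayProfile(evidence, entry, shortlist, config)
  cx <- scoreContext(entry, context, config)
  criteria <- c(mk$points, if (!is.null(pw)) pw$points, cx$points)
  items <- c(mk$items, if (!is.null(pw)) pw$items, cx$items)
  new("ScoreBreakdown", candidate = entry@cellType,
      criteria = criteria, items = items,
      markerComponent = sum(mk$points),
      pathwayComponent = if (is.null(pw)) numeric(0) else sum(pw$points),
      contextComponent = sum(cx$points),
      total = sum(criteria))
}

# Serialize a breakdown into the plain-list form embedded in reports.
breakdownToList <- function(breakdown) {
  out <- list(
    candidate = breakdown@candidate,
    criteria = lapply(as.list(breakdown@criteria), as.numeric),
    evidence = lapply(breakdown@items, as.character),
    marker_component = as.numeric(breakdown@markerComponent),
    context_component = as.numeric(breakdown@contextComponent),
    total = as.numeric(breakdown@total))
  if (length(breakdown@pathwayComponent))
    out$pathway_component <- as.numeric(breakdown@pathwayComponent)
  out
}

breakdownFromList <- function(x) {
  new("ScoreBreakdown", candidate = x$candidate,
      criteria = unlist(lapply(x$criteria, as.numeric)),
      items = lapply(x$evidence, as.character),
      markerComponent = as.numeric(x$marker_component),
      pathwayComponent = if (is.null(x$pathway_component)) numeric(0)
                         else as.numeric(x$pathway_component),
      contextComponent = as.numeric(x$context_component),
      total = as.numeric(x$total))
}
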