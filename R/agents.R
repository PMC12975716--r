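#' Prospector: shortlist plausible cell types from context
#'
#' Filters the knowledge base to entries plausible in the context tissue
#' (entries listing no tissue are plausible anywhere; an empty context
#' tissue keeps every entry), orders them by canonical name, and
#' truncates to `limit`. When a nonempty tissue matches no entry the
#' shortlist falls back to the whole knowledge base (flagged in the
#' provenance) so downstream stages always have candidates to audit.
#'
#' @param context a [BiologicalContext-class].
#' @param kb a nonempty [MarkerKnowledgeBase-class].
#' @param limit maximum shortlist length (default 10).
#' @return a [CandidateShortlist-class].
#' @export
prospect <- function(context, kb, limit = 10) {
  if (length(kb@entries) == 0L) stop("knowledge base is empty")
  tissue <- context@tissue
  plausible <- vapply(kb@entries, function(e) {
    !nzchar(tissue) || length(e@tissues) == 0L ||
      normalizeLabel(tissue) %in% normalizeLabel(e@tissues)
  }, logical(1))
  note <- if (!nzchar(tissue)) "no tissue restriction"
          else sprintf("plausible in tissue '%s'", tissue)
  nm <- names(kb@entries)[plausible]
  if (!length(nm)) {
    nm <- names(kb@entries)
    note <- sprintf("fallback: no entry lists tissue '%s'", tissue)
  }
  nm <- head(sortC(nm), limit)
  new("CandidateShortlist", names = nm,
      provenance = stats::setNames(rep(note, length(nm)), nm))
}

#' Reference rubric backend
#'
#' The deterministic reference implementation of the backend contract:
#' scores every shortlisted entry with [scoreCandidate()], with the other
#' shortlisted entries as competitors.
#'
#' @return an [AnnotationBackend-class] (deterministic).
#' @export
rubricBackend <- function() {
  new("AnnotationBackend", name = "rubric", deterministic = TRUE,
      scoreFun = function(entries, evidence, context, config) {
        lapply(seq_along(entries), function(i)
          scoreCandidate(evidence, entries[[i]],
                         shortlist = entries[-i], context = context,
                         config = config))
      })
}

# Canonical request fingerprint shared by the recorder and the replayer.
backendRequestHash <- function(entries, evidence, context) {
  fnv1a32(canonicalJSON(list(
    cluster = evidence@clusterId,
    shortlist = vapply(entries, function(e) e@cellType, character(1)),
    top_genes = topGenes(evidence),
    significant_terms = if (is.null(evidence@enrichment)) character(0)
      else as.character(evidence@enrichment$term[
        evidence@enrichment$adjusted_p < evidence@sigCut]),
    tissue = context@tissue, condition = context@condition,
    species = context@species)))
}

#' Replay backend: answer only from a recorded fixture
#'
#' Stands in for a remote reasoning backend (e.g. an LLM adapter) in
#' tests: responses are read from a JSON recording keyed by a
#' request hash; a cache miss is a hard error, never a silent fallback.
#'
#' @param path JSON recording produced by [recordReplayFixture()].
#' @return an [AnnotationBackend-class] (deterministic by construction).
#' @export
replayBackend <- function(path) {
  if (!file.exists(path)) stop("replay recording not found: ", path)
  recording <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                  simplifyVector = FALSE)
  new("AnnotationBackend", name = "replay", deterministic = TRUE,
      scoreFun = function(entries, evidence, context, config) {
        key <- backendRequestHash(entries, evidence, context)
        if (is.null(recording[[key]]))
          stop("replay cache miss for request ", key,
               " (cluster '", evidence@clusterId, "')")
        lapply(recording[[key]], breakdownFromList)
      })
}

#' Record an inner backend's responses into a replay fixture
#'
#' Runs `backend` on each evidence bundle and appends the serialized
#' responses to a JSON recording usable by [replayBackend()].
#'
#' @param path output JSON path.
#' @param shortlist a [CandidateShortlist-class].
#' @param evidences list of [ClusterEvidence-class].
#' @param context a [BiologicalContext-class].
#' @param kb the knowledge base.
#' @param config a [RubricConfig-class].
#' @param backend backend to record (default the rubric engine).
#' @return `path`, invisibly.
#' @export
recordReplayFixture <- function(path, shortlist, evidences, context, kb,
                                config = rubricConfig(),
                                backend = rubricBackend()) {
  recording <- list()
  for (ev in evidences) {
    entries <- lapply(shortlist@names, kbEntry, kb = kb)
    key <- backendRequestHash(entries, ev, context)
    resp <- backend@scoreFun(entries, ev, context, config)
    recording[[key]] <- lapply(resp, breakdownToList)
  }
  writeLines(as.character(jsonlite::toJSON(recording, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             path)
  invisible(path)
}

#' Insightor: score every shortlisted candidate against the evidence
#'
#' @param shortlist a nonempty [CandidateShortlist-class].
#' @param evidence a [ClusterEvidence-class].
#' @param context a [BiologicalContext-class].
#' @param kb the knowledge base the shortlist names resolve in.
#' @param config a [RubricConfig-class].
#' @param backend an [AnnotationBackend-class] (default the rubric
#'   engine).
#' @return list of [ScoreBreakdown-class], one per shortlisted candidate.
#' @export
insight <- function(shortlist, evidence, context, kb,
                    config = rubricConfig(), backend = rubricBackend()) {
  if (!length(shortlist@names)) stop("shortlist is empty")
  entries <- lapply(shortlist@names, kbEntry, kb = kb)
  backend@scoreFun(entries, evidence, context, config)
}

confidenceTier <- function(total, tiers = c(high = 70, medium = 40)) {
  if (total >= tiers[["high"]]) "high"
  else if (total >= tiers[["medium"]]) "medium"
  else "low"
}

# Template-generated reasoning: one plain sentence per triggered criterion.
reasoningText <- function(breakdown) {
  tpl <- c(
    marker_match = "broad markers matched in the top DEGs (%s): %+g",
    narrow_marker = "narrow high-specificity markers matched (%s): %+g",
    shared_marker = "markers shared with another candidate (%s): %+g",
    negative_marker = "negative markers unexpectedly present (%s): %+g",
    pathway_state = "enriched pathways fit the cell state (%s): %+g",
    pathway_type = "enriched pathways fit the cell type (%s): %+g",
    pathway_shared = "pathways also characteristic of another candidate (%s): %+g",
    pathway_conflict = "conflicting pathways enriched (%s): %+g",
    context_type = "cell type plausible in the given context (%s): %+g",
    context_state = "cell state plausible in the given context (%s): %+g",
    context_implausible = "implausible in the given context (%s): %+g")
  parts <- character(0)
  for (crit in names(breakdown@criteria)) {
    pts <- breakdown@criteria[[crit]]
    if (pts == 0) next
    what <- breakdown@items[[crit]]
    parts <- c(parts, sprintf(tpl[[crit]],
                              if (length(what)) paste(what, collapse = ", ")
                              else "context", pts))
  }
  if (!length(parts)) parts <- "no rubric criterion triggered"
  paste0(paste(parts, collapse = "; "), ".")
}

absentSlot <- function(slot) list(slot = as.numeric(slot), absent = TRUE)

#' Reviewer: rank candidates and build one cluster's report record
#'
#' Sorts the scored candidates by total (descending, ties by name
#' ascending), keeps exactly three slots (explicitly marking absent slots
#' when fewer than three candidates exist), assigns confidence tiers by
#' total thresholds, and flags the cluster for manual follow-up when the
#' top two totals differ by less than `margin` points. Each retained
#' candidate carries its matched key markers, additional knowledge-base
#' markers not in the top DEGs as validation ("gold standard")
#' suggestions, template-generated reasoning, and the full score
#' breakdown.
#'
#' @param breakdowns nonempty list of [ScoreBreakdown-class].
#' @param evidence the cluster's [ClusterEvidence-class].
#' @param kb the knowledge base.
#' @param margin low-agreement margin in points (default 10).
#' @param tiers named numeric thresholds `c(high = , medium = )`.
#' @return a plain-list cluster record (see [AnnotationReport-class]).
#' @export
reviewCluster <- function(breakdowns, evidence, kb, margin = 10,
                          tiers = c(high = 70, medium = 40)) {
  if (!length(breakdowns)) stop("need at least one scored candidate")
  totals <- vapply(breakdowns, breakdownTotal, numeric(1))
  nm <- vapply(breakdowns, function(b) b@candidate, character(1))
  ord <- orderC(-totals, nm)
  breakdowns <- breakdowns[ord]
  totals <- totals[ord]
  top <- topGenes(evidence)
  candidates <- vector("list", 3L)
  for (i in 1:3) {
    if (i > length(breakdowns)) {
      candidates[[i]] <- absentSlot(i)
      next
    }
    b <- breakdowns[[i]]
    entry <- if (b@candidate %in% kbNames(kb)) kbEntry(kb, b@candidate)
             else NULL
    keyMarkers <- sortC(unique(unlist(
      b@items[c("marker_match", "narrow_marker")], use.names = FALSE)))
    validation <- if (is.null(entry)) character(0)
      else sortC(setdiff(positiveMarkers(entry), top))
    stateHits <- b@items$context_state
    candidates[[i]] <- list(
      slot = as.numeric(i), absent = FALSE, name = b@candidate,
      cl_id = if (is.null(entry)) "" else entry@clId,
      state = if (length(stateHits)) parseStateTag(stateHits[1])$label
              else "",
      confidence = confidenceTier(b@total, tiers),
      key_markers = as.character(keyMarkers),
      validation_markers = as.character(validation),
      reasoning = reasoningText(b),
      breakdown = breakdownToList(b))
  }
  sig <- if (is.null(evidence@enrichment)) character(0)
    else as.character(evidence@enrichment$term[
      evidence@enrichment$adjusted_p < evidence@sigCut])
  list(cluster_id = evidence@clusterId,
       flagged = length(totals) >= 2L && (totals[1] - totals[2]) < margin,
       evidence = list(top_genes = as.character(top),
                       n_genes = as.numeric(length(top)),
                       significant_terms = as.character(sig)),
       candidates = candidates)
}

#' Standardize predicted labels to canonical knowledge-base names
#'
#' Every label is passed through [resolveLabel()]; unresolved labels are
#' kept verbatim and reported with a warning, so naming is uniform across
#' clusters wherever the knowledge base can vouch for it.
#'
#' @param labels character vector of predicted labels.
#' @param kb a [MarkerKnowledgeBase-class].
#' @return character vector of harmonized labels (same length/names).
#' @export
standardizeLabels <- function(labels, kb) {
  out <- vapply(labels, function(l) {
    r <- resolveLabel(l, kb)
    if (is.na(r)) l else r
  }, character(1))
  unresolved <- labels[is.na(vapply(labels, resolveLabel, character(1),
                                    kb = kb))]
  if (length(unresolved))
    warning("label(s) not resolvable in the knowledge base, kept verbatim: ",
            paste(unique(unresolved), collapse = ", "))
  out
}

#' Annotate every cluster: the full three-stage pipeline
#'
#' Prospector shortlists candidates from the context (padded with further
#' knowledge-base entries so at least three candidates are scored
#' whenever the knowledge base allows), then per cluster the Insightor
#' scores the shortlist against the cluster's evidence and the Reviewer
#' ranks it into three slots. Clusters are independent: failures are
#' isolated into per-cluster error records, and results are assembled in
#' cluster-id order so the output is invariant to processing order.
#' `workers > 1` processes clusters concurrently via forked processes;
#' serial and concurrent runs yield identical results.
#'
#' @param data a `SingleCellExperiment` from [countsWithClusters()].
#' @param kb a nonempty [MarkerKnowledgeBase-class].
#' @param collection gene-set collection for ORA, or NULL for
#'   two-component scoring.
#' @param context a [BiologicalContext-class].
#' @param config a [RubricConfig-class].
#' @param topN top DEGs per cluster (default 20).
#' @param sigCut enrichment significance cut (default 0.05).
#' @param shortlistLimit Prospector limit (default 10).
#' @param margin low-agreement flag margin in points (default 10).
#' @param tiers confidence-tier thresholds.
#' @param backend an [AnnotationBackend-class].
#' @param workers number of concurrent workers (default 1 = serial).
#' @return list with `clusters` (per-cluster records in cluster-id
#'   order), `shortlist`, and `params` (the effective configuration);
#'   pass to [buildReport()].
#' @export
annotateAll <- function(data, kb, collection = NULL,
                        context = biologicalContext(),
                        config = rubricConfig(), topN = 20, sigCut = 0.05,
                        shortlistLimit = 10, margin = 10,
                        tiers = c(high = 70, medium = 40),
                        backend = rubricBackend(), workers = 1) {
  shortlist <- prospect(context, kb, limit = shortlistLimit)
  # pad so every cluster can fill three slots whenever the KB is big enough
  need <- min(3L, length(kb@entries))
  if (length(shortlist@names) < need) {
    extra <- head(setdiff(sortC(kbNames(kb)), shortlist@names),
                  need - length(shortlist@names))
    shortlist <- new("CandidateShortlist",
                     names = c(shortlist@names, extra),
                     provenance = c(shortlist@provenance,
                                    stats::setNames(
                                      rep("padding: fills the three report slots",
                                          length(extra)), extra)))
  }
  clusters <- sortC(unique(clusterIds(data)))
  oneCluster <- function(cl) {
    tryCatch({
      ev <- clusterEvidenceFor(data, cl, collection = collection,
                               context = context, topN = topN,
                               sigCut = sigCut)
      bd <- insight(shortlist, ev, context, kb, config, backend)
      reviewCluster(bd, ev, kb, margin = margin, tiers = tiers)
    }, error = function(e)
      list(cluster_id = as.character(cl),
           error = conditionMessage(e)))
  }
  records <- if (workers > 1 &&
                 requireNamespace("parallel", quietly = TRUE) &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(clusters, oneCluster, mc.cores = workers)
  } else {
    lapply(clusters, oneCluster)
  }
  names(records) <- clusters
  params <- list(top_n = as.numeric(topN), sig_cut = as.numeric(sigCut),
                 shortlist_limit = as.numeric(shortlistLimit),
                 margin = as.numeric(margin),
                 tier_high = as.numeric(tiers[["high"]]),
                 tier_medium = as.numeric(tiers[["medium"]]),
                 tissue = context@tissue, condition = context@condition,
                 species = context@species,
                 has_collection = !is.null(collection),
                 rubric = rubricToList(config))
  list(clusters = records, shortlist = shortlist, params = params,
       backend = backend@name)
}
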