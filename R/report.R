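REPORT_SCHEMA_VERSION <- "1.0"

# Coerce parsed-JSON (or freshly built) records into one canonical R form
# so a report -> JSON -> report round trip is exactly identical:
# known array fields become character vectors (character(0) when empty),
# known numeric fields become doubles.
chrVecFields <- c("top_genes", "significant_terms", "key_markers",
                  "validation_markers")
numScalarFields <- c("slot", "n_genes", "marker_component",
                     "pathway_component", "context_component", "total",
                     "top_n", "sig_cut", "shortlist_limit", "margin",
                     "tier_high", "tier_medium", "seed")

normalizeRecord <- function(x) {
  if (!is.list(x)) return(x)
  nms <- names(x)
  if (is.null(nms)) nms <- rep("", length(x))
  for (i in seq_along(x)) {
    nm <- nms[i]
    v <- x[[i]]
    if (nm %in% chrVecFields) {
      x[[i]] <- as.character(unlist(v, use.names = FALSE))
    } else if (nm %in% numScalarFields) {
      x[[i]] <- as.numeric(v)
    } else if (nm %in% c("criteria", "rubric")) {
      x[[i]] <- lapply(v, as.numeric)
    } else if (nm == "breakdown") {
      v$criteria <- lapply(v$criteria, as.numeric)
      v$evidence <- lapply(v$evidence, function(e)
        as.character(unlist(e, use.names = FALSE)))
      for (f in intersect(names(v), numScalarFields))
        v[[f]] <- as.numeric(v[[f]])
      x[[i]] <- v
    } else if (is.list(v)) {
      x[[i]] <- normalizeRecord(v)
    }
  }
  x
}

#' Build the audit-ready annotation report
#'
#' Wraps the output of [annotateAll()] with run metadata: schema version,
#' backend identity, seed, a fingerprint of the effective configuration,
#' and a timestamp (an explicit argument, so reports of identical runs
#' can be made byte-identical).
#'
#' @param pipeline the list returned by [annotateAll()].
#' @param seed the seed the run was executed under (recorded, not
#'   applied).
#' @param timestamp character timestamp; default the current UTC time.
#' @return an [AnnotationReport-class].
#' @export
buildReport <- function(pipeline, seed = NA_real_,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                           tz = "UTC")) {
  params <- normalizeRecord(pipeline$params)
  metadata <- c(
    list(schema_version = REPORT_SCHEMA_VERSION,
         backend = pipeline$backend),
    if (!is.na(seed)) list(seed = as.numeric(seed)),
    list(config_hash = fnv1a32(canonicalJSON(params)),
         timestamp = as.character(timestamp),
         params = params))
  clusters <- lapply(pipeline$clusters, normalizeRecord)
  new("AnnotationReport", metadata = metadata, clusters = clusters)
}

#' Serialize / deserialize an AnnotationReport as canonical JSON
#'
#' `reportToJSON()` emits the versioned canonical schema;
#' `reportFromJSON()` parses it back. The round trip is lossless:
#' `reportFromJSON(reportToJSON(r))` is identical to `r`.
#'
#' @param report an [AnnotationReport-class].
#' @param txt JSON text (or a file path for `readReport()`).
#' @param path output / input file path.
#' @return JSON character scalar, or an [AnnotationReport-class].
#' @export
reportToJSON <- function(report) {
  as.character(jsonlite::toJSON(
    list(metadata = report@metadata, clusters = report@clusters),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE))
}

#' @rdname reportToJSON
#' @export
reportFromJSON <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  new("AnnotationReport", metadata = normalizeRecord(x$metadata),
      clusters = lapply(x$clusters, normalizeRecord))
}

#' @rdname reportToJSON
#' @export
writeReport <- function(report, path) {
  writeLines(reportToJSON(report), path)
  invisible(path)
}

#' @rdname reportToJSON
#' @export
readReport <- function(path) {
  reportFromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Render an AnnotationReport as human-readable markdown
#'
#' Contains every candidate name and total present in the JSON, the
#' evidence summaries, confidence tiers, validation markers, and the
#' template-generated reasoning.
#'
#' @param report an [AnnotationReport-class].
#' @return character scalar of markdown text.
#' @export
renderReportMarkdown <- function(report) {
  md <- c("# Cell-type annotation report", "",
          sprintf("- backend: %s", report@metadata$backend),
          sprintf("- seed: %s", report@metadata$seed),
          sprintf("- config hash: %s", report@metadata$config_hash),
          sprintf("- generated: %s", report@metadata$timestamp), "")
  for (rec in report@clusters) {
    md <- c(md, sprintf("## Cluster %s", rec$cluster_id), "")
    if (!is.null(rec$error)) {
      md <- c(md, sprintf("**ERROR**: %s", rec$error), "")
      next
    }
    if (isTRUE(rec$flagged))
      md <- c(md, "*Flagged: low agreement between top candidates — manual follow-up suggested.*", "")
    md <- c(md, sprintf("Top DEGs: %s",
                        paste(rec$evidence$top_genes, collapse = ", ")))
    if (length(rec$evidence$significant_terms))
      md <- c(md, sprintf("Significant pathways: %s",
                          paste(rec$evidence$significant_terms,
                                collapse = ", ")))
    md <- c(md, "")
    for (cand in rec$candidates) {
      if (isTRUE(cand$absent)) {
        md <- c(md, sprintf("### Slot %d: (absent — knowledge base too small)",
                            cand$slot), "")
        next
      }
      md <- c(md,
        sprintf("### %d. %s (total %g, confidence %s)", cand$slot,
                cand$name, cand$breakdown$total, cand$confidence),
        if (nzchar(cand$cl_id)) sprintf("- ontology: %s", cand$cl_id),
        if (nzchar(cand$state)) sprintf("- state: %s", cand$state),
        sprintf("- key markers: %s",
                if (length(cand$key_markers))
                  paste(cand$key_markers, collapse = ", ") else "(none)"),
        sprintf("- validation markers: %s",
                if (length(cand$validation_markers))
                  paste(cand$validation_markers, collapse = ", ")
                else "(none)"),
        sprintf("- reasoning: %s", cand$reasoning),
        "")
    }
  }
  paste(md, collapse = "\n")
}

#' Cluster-by-cell-type score matrix
#'
#' Rows are clusters, columns the lexicographic union of candidate cell
#' types across the report, values the breakdown totals; a cluster /
#' cell-type pair without a candidate is `NA` (never a fabricated score).
#'
#' @param report a nonempty [AnnotationReport-class].
#' @return numeric matrix with cluster rownames and cell-type colnames.
#' @export
scoreMatrix <- function(report) {
  if (!length(report@clusters)) stop("report has no clusters")
  recs <- report@clusters
  types <- sortC(unique(unlist(lapply(recs, function(rec) {
    if (!is.null(rec$error)) return(character(0))
    vapply(Filter(function(cand) !isTRUE(cand$absent), rec$candidates),
           function(cand) cand$name, character(1))
  }))))
  clusters <- unname(vapply(recs, function(rec) rec$cluster_id,
                            character(1)))
  m <- matrix(NA_real_, nrow = length(clusters), ncol = length(types),
              dimnames = list(clusters, types))
  for (rec in recs) {
    if (!is.null(rec$error)) next
    for (cand in rec$candidates)
      if (!isTRUE(cand$absent))
        m[rec$cluster_id, cand$name] <- cand$breakdown$total
  }
  m
}

#' Write a score matrix as TSV (missing values as empty cells)
#'
#' @param m matrix from [scoreMatrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeScoreMatrix <- function(m, path) {
  df <- data.frame(cluster = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Heat map of the cluster-by-cell-type score matrix
#'
#' Cosmetic convenience around `pheatmap` for comparing confidence across
#' clusters and spotting similarities between putative cell types.
#'
#' @param m matrix from [scoreMatrix()].
#' @param ... passed to `pheatmap::pheatmap`.
#' @return the pheatmap object, invisibly.
#' @export
plotScoreHeatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotScoreHeatmap needs the 'pheatmap' package")
  invisible(pheatmap::pheatmap(m, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}
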