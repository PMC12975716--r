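kbColumns <- c("cell_type", "cl_id", "broad_markers", "narrow_markers",
               "negative_markers", "tissues", "states", "pathways_type",
               "pathways_state", "synonyms")

#' Load a marker knowledge base from TSV or JSON
#'
#' The TSV dialect has the fixed header `cell_type, cl_id, broad_markers,
#' narrow_markers, negative_markers, tissues, states, pathways_type,
#' pathways_state, synonyms`; list cells are `|`-delimited and lines
#' starting with `#` are comments. The JSON form mirrors the same fields
#' as an array of objects. Gene symbols are upper-cased on load.
#'
#' A duplicate canonical name, a gene listed as both positive and negative
#' for the same entry, or a synonym resolving to two entries is a hard
#' error. An empty file yields an empty knowledge base with a warning.
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return a [MarkerKnowledgeBase-class].
#' @seealso [writeKnowledgeBase()], [resolveLabel()]
#' @export
loadKnowledgeBase <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  if (!file.exists(path)) stop("knowledge-base file not found: ", path)
  rows <- if (format == "json") {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[!grepl("^\\s*#", txt)]
    if (!any(nzchar(trimws(txt)))) list()
    else jsonlite::fromJSON(paste(txt, collapse = "\n"),
                            simplifyDataFrame = FALSE)
  } else {
    readKBTsv(path)
  }
  if (length(rows) == 0L) {
    warning("knowledge-base file '", path, "' is empty")
    return(markerKnowledgeBase())
  }
  nm <- vapply(rows, function(r) trimws(as.character(r$cell_type)),
               character(1))
  dup <- which(duplicated(normalizeLabel(nm)))
  if (length(dup)) {
    first <- match(normalizeLabel(nm)[dup[1]], normalizeLabel(nm))
    stop(sprintf(
      "duplicate canonical cell type '%s' (rows %d and %d)",
      nm[dup[1]], first, dup[1]))
  }
  entries <- lapply(rows, function(r) {
    listify <- function(x) {
      if (is.null(x)) character(0)
      else if (length(x) > 1L) as.character(x)
      else splitListCell(as.character(x))
    }
    markerEntry(cellType = r$cell_type,
                clId = if (is.null(r$cl_id) || is.na(r$cl_id)) ""
                       else as.character(r$cl_id),
                broadMarkers = listify(r$broad_markers),
                narrowMarkers = listify(r$narrow_markers),
                negativeMarkers = listify(r$negative_markers),
                tissues = listify(r$tissues), states = listify(r$states),
                pathwaysType = listify(r$pathways_type),
                pathwaysState = listify(r$pathways_state),
                synonyms = listify(r$synonyms))
  })
  markerKnowledgeBase(entries)
}

readKBTsv <- function(path) {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               colClasses = "character", check.names = FALSE,
               blank.lines.skip = TRUE),
    error = function(e) NULL)
  if (is.null(df) || (nrow(df) == 0L && ncol(df) <= 1L)) return(list())
  missing <- setdiff(kbColumns, names(df))
  if (length(missing))
    stop("knowledge-base TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, kbColumns]))
}

#' Write a marker knowledge base to TSV or JSON
#'
#' Inverse of [loadKnowledgeBase()]: a load -> save -> load round trip is
#' content-identical.
#'
#' @param kb a [MarkerKnowledgeBase-class].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  rows <- lapply(kb@entries, function(e) list(
    cell_type = e@cellType, cl_id = e@clId,
    broad_markers = e@broadMarkers, narrow_markers = e@narrowMarkers,
    negative_markers = e@negativeMarkers, tissues = e@tissues,
    states = e@states, pathways_type = e@pathwaysType,
    pathways_state = e@pathwaysState, synonyms = e@synonyms))
  if (format == "json") {
    writeLines(as.character(jsonlite::toJSON(unname(rows), digits = NA,
                                             auto_unbox = FALSE,
                                             pretty = TRUE)), path)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(lapply(stats::setNames(kbColumns, kbColumns), function(cn) {
        v <- r[[cn]]
        if (cn %in% c("cell_type", "cl_id")) as.character(v)
        else joinListCell(v)
      }), stringsAsFactors = FALSE, check.names = FALSE)
    }))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Resolve a free-text label to a canonical knowledge-base name
#'
#' Matching is case-insensitive and whitespace/hyphen-normalized against
#' canonical names and synonyms. No-match is a value (`NA_character_`),
#' not an error, and resolution is idempotent: a resolved name resolves to
#' itself.
#'
#' @param label a cell-type label.
#' @param kb a [MarkerKnowledgeBase-class].
#' @return the canonical name, or `NA_character_` if the label does not
#'   resolve.
#' @examples
#' kb <- markerKnowledgeBase(markerEntry("B cell", synonyms = "B cells"))
#' resolveLabel("b-cells", kb)  # "B cell"
#' @export
resolveLabel <- function(label, kb) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label)))
    return(NA_character_)
  key <- normalizeLabel(label)
  for (e in kb@entries)
    if (key %in% normalizeLabel(c(e@cellType, e@synonyms)))
      return(e@cellType)
  NA_character_
}

# ---- ontology -------------------------------------------------------------

#' Load a cell ontology graph from OBO or an edge-list TSV
#'
#' The edge-list dialect is a two-column child/parent TSV (`#` comments
#' tolerated; an optional `child<TAB>parent` header is skipped; a row with
#' an empty second column declares an isolated term). The OBO reader is a
#' minimal parser of `[Term]` stanzas (`id`, `name`, `is_a`); an `is_a`
#' pointing at an undeclared term is an error. Cycles are a hard error
#' naming the cycle.
#'
#' @param path file path.
#' @param format `"obo"` or `"edge_tsv"`; default guessed from the
#'   extension.
#' @param broadCategory optional named character (term id -> category
#'   label) enabling the partial-match-by-category rule of [agreement()],
#'   or a path to a two-column TSV (term, category).
#' @return an [OntologyGraph-class].
#' @export
loadOntology <- function(path, format = c("auto", "obo", "edge_tsv"),
                         broadCategory = character()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo"
              else "edge_tsv"
  if (!file.exists(path)) stop("ontology file not found: ", path)
  if (is.character(broadCategory) && length(broadCategory) == 1L &&
      is.null(names(broadCategory)) && file.exists(broadCategory)) {
    bc <- read.delim(broadCategory, header = FALSE, comment.char = "#",
                     colClasses = "character")
    broadCategory <- stats::setNames(bc[[2]], bc[[1]])
  }
  if (format == "obo") {
    parsed <- parseOboTerms(path)
    undeclared <- setdiff(unique(parsed$edges$parent), parsed$terms)
    if (length(undeclared))
      stop("OBO is_a references undeclared term(s): ",
           paste(undeclared, collapse = ", "))
    ontologyGraph(parsed$terms, parsed$edges, termNames = parsed$names,
                  broadCategory = broadCategory)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (length(lines) && grepl("^child\\tparent$", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    child <- vapply(parts, function(p) trimws(p[1]), character(1))
    parent <- vapply(parts, function(p)
      if (length(p) >= 2L) trimws(p[2]) else "", character(1))
    hasEdge <- nzchar(parent)
    terms <- unique(c(child, parent[hasEdge]))
    ontologyGraph(terms,
                  data.frame(child = child[hasEdge],
                             parent = parent[hasEdge],
                             stringsAsFactors = FALSE),
                  broadCategory = broadCategory)
  }
}

parseOboTerms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); nm <- character(0)
  edges <- list(child = character(0), parent = character(0))
  inTerm <- FALSE; curId <- NA_character_
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)            # strip OBO comments
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) { inTerm <- identical(ln, "[Term]"); curId <- NA; next }
    if (!inTerm) next
    if (grepl("^id:", ln)) {
      curId <- trimws(sub("^id:", "", ln))
      terms <- c(terms, curId)
    } else if (grepl("^name:", ln) && !is.na(curId)) {
      nm[curId] <- trimws(sub("^name:", "", ln))
    } else if (grepl("^is_a:", ln) && !is.na(curId)) {
      edges$child <- c(edges$child, curId)
      edges$parent <- c(edges$parent, trimws(sub("^is_a:", "", ln)))
    }
  }
  list(terms = unique(terms), names = nm,
       edges = data.frame(child = edges$child, parent = edges$parent,
                          stringsAsFactors = FALSE))
}

# Depth-first search for a cycle; returns the cycle as a term sequence or
# NULL if the graph is acyclic.
findCycle <- function(graph) {
  state <- stats::setNames(rep(0L, length(graph@terms)), graph@terms)
  path <- character(0)
  visit <- function(id) {
    if (state[[id]] == 1L) return(c(path[which(path == id)[1]:length(path)], id))
    if (state[[id]] == 2L) return(NULL)
    state[[id]] <<- 1L
    path <<- c(path, id)
    for (p in graph@parents[[id]]) {
      res <- visit(p)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[id]] <<- 2L
    NULL
  }
  for (t in graph@terms) {
    res <- visit(t)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Ancestor terms of an ontology term
#'
#' Full transitive is_a closure (any distance), excluding the term itself.
#' An unknown term yields an empty set.
#'
#' @param graph an [OntologyGraph-class].
#' @param id term id.
#' @return character vector of ancestor ids (byte-sorted).
#' @export
ontologyAncestors <- function(graph, id) {
  if (!id %in% graph@terms) return(character(0))
  seen <- character(0)
  frontier <- graph@parents[[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph@parents[frontier], use.names = FALSE)), seen)
  }
  sortC(seen)
}

#' Broad-category label of an ontology term
#'
#' @param graph an [OntologyGraph-class].
#' @param id term id.
#' @return the configured category label or `NA_character_`.
#' @export
ontologyCategory <- function(graph, id) {
  if (length(graph@broadCategory) && id %in% names(graph@broadCategory))
    unname(graph@broadCategory[[id]])
  else NA_character_
}
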