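#' Generate a seeded clustered count matrix with planted marker signatures
#'
#' One cluster is simulated per knowledge-base entry (clusters named
#' `C1`, `C2`, ... in canonical-name order). Every gene in every cell is
#' negative binomial with the baseline mean and common dispersion; a
#' planted type's positive markers (broad plus narrow) have their mean
#' multiplied by `markerFold` in that type's own cluster, and its
#' negative markers are multiplied by `negativeSuppression`. The gene
#' list is the union of all knowledge-base markers plus background genes
#' named `GBG0001...` (a namespace that cannot collide with real
#' symbols). Markers shared between planted types are allowed and
#' logged — they exercise the shared-marker deduction downstream.
#'
#' @param spec a [SynthSpec-class].
#' @return list with `data` (a `SingleCellExperiment`, see
#'   [countsWithClusters()]) and `truth` (named character, cluster id ->
#'   planted cell type).
#' @examples
#' kb <- markerKnowledgeBase(
#'   markerEntry("B cell", broadMarkers = c("CD19", "MS4A1")),
#'   markerEntry("T cell", broadMarkers = c("CD3D", "CD3E")))
#' sim <- generateSynthData(synthSpec(kb, cellsPerCluster = 10, seed = 7))
#' table(clusterIds(sim$data))
#' @export
generateSynthData <- function(spec) {
  kb <- spec@kb
  typeNames <- kbNames(kb)
  overlap <- table(unlist(lapply(kb@entries, positiveMarkers)))
  if (any(overlap > 1))
    message("synth: marker(s) shared across planted types: ",
            paste(names(overlap)[overlap > 1], collapse = ", "))
  markerGenes <- sortC(unique(unlist(lapply(kb@entries, function(e)
    c(e@broadMarkers, e@narrowMarkers, e@negativeMarkers)))))
  bg <- if (spec@nBackgroundGenes > 0)
    sprintf("GBG%04d", seq_len(spec@nBackgroundGenes)) else character(0)
  genes <- c(markerGenes, bg)
  nPer <- spec@cellsPerCluster
  nCells <- nPer * length(typeNames)
  clusterNames <- sprintf("C%d", seq_along(typeNames))
  truth <- stats::setNames(typeNames, clusterNames)
  # per-gene, per-cluster NB means
  mu <- matrix(spec@baselineMean, nrow = length(genes),
               ncol = length(typeNames), dimnames = list(genes, NULL))
  for (j in seq_along(typeNames)) {
    e <- kb@entries[[typeNames[j]]]
    mu[positiveMarkers(e), j] <- spec@baselineMean * spec@markerFold
    mu[e@negativeMarkers, j] <-
      spec@baselineMean * spec@negativeSuppression
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec@seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  counts <- matrix(0L, nrow = length(genes), ncol = nCells,
                   dimnames = list(genes,
                                   sprintf("cell%04d", seq_len(nCells))))
  clusters <- rep(clusterNames, each = nPer)
  for (j in seq_along(typeNames)) {
    cols <- which(clusters == clusterNames[j])
    counts[, cols] <- rnbinom(length(genes) * nPer, size = spec@dispersion,
                              mu = rep(mu[, j], times = nPer))
  }
  list(data = countsWithClusters(counts, clusters), truth = truth)
}

#' Reference labels from the simulator's ground truth
#'
#' Projects the cluster -> planted-type map into the two-column reference
#' TSV consumed by the evaluation stage.
#'
#' @param truth named character, cluster id -> cell type (from
#'   [generateSynthData()]).
#' @param path optional output TSV path.
#' @return data.frame with columns cluster_id, reference_label; written
#'   to `path` when given.
#' @export
makeReferenceLabels <- function(truth, path = NULL) {
  df <- data.frame(cluster_id = names(truth),
                   reference_label = unname(truth),
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  df
}

#' Write a simulated dataset as CSV + TSV fixture files
#'
#' Emits the dense cells-x-genes counts CSV, the two-column cell/cluster
#' TSV, and the reference-label TSV, matching the evidence module's
#' readers.
#'
#' @param sim result of [generateSynthData()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
writeSynthData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  countsPath <- file.path(dir, "counts.csv")
  clustersPath <- file.path(dir, "clusters.tsv")
  refPath <- file.path(dir, "reference_labels.tsv")
  m <- SummarizedExperiment::assay(sim$data, "counts")
  df <- data.frame(cell = colnames(m), t(as.matrix(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, countsPath, row.names = FALSE, quote = FALSE)
  write.table(data.frame(colnames(m), clusterIds(sim$data)), clustersPath,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  makeReferenceLabels(sim$truth, refPath)
  invisible(c(counts = countsPath, clusters = clustersPath,
              reference = refPath))
}
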