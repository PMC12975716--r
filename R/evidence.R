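#' Build the counts-with-clusters container
#'
#' Wraps a genes x cells count matrix and per-cell cluster assignments in
#' a [SingleCellExperiment::SingleCellExperiment] with a `counts` assay
#' and a `cluster` column in `colData` — the input contract of the
#' evidence stage.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts with unique rownames (gene symbols).
#' @param clusters character/factor vector of cluster ids, one per cell
#'   (recycled names checked against `colnames(counts)` when both named).
#' @return a `SingleCellExperiment`.
#' @export
countsWithClusters <- function(counts, clusters) {
  if (is.null(rownames(counts)))
    stop("counts must have gene symbols as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("gene names must be unique")
  if (length(clusters) != ncol(counts))
    stop("need one cluster id per cell: got ", length(clusters),
         " for ", ncol(counts), " cells")
  if (any(is.na(clusters) | !nzchar(as.character(clusters))))
    stop("every cell must have a cluster id")
  if (min(counts) < 0) stop("counts must be non-negative")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cluster = as.character(clusters)))
  rownames(sce) <- toupper(rownames(counts))
  sce
}

#' Cluster ids of a counts container
#' @param data a `SingleCellExperiment` built by [countsWithClusters()].
#' @return character vector, one id per cell.
#' @export
clusterIds <- function(data) {
  as.character(SummarizedExperiment::colData(data)$cluster)
}

#' Read counts + cluster labels from files
#'
#' `readCountsCSV()` expects a dense CSV with cells as rows (first column
#' cell id, remaining columns genes). `readCountsMTX()` expects a
#' MatrixMarket file plus one-column gene and cell text files
#' (genes x cells orientation). Both take cluster assignments from a
#' two-column TSV (cell, cluster; `#` comments and an optional header
#' tolerated).
#'
#' @param countsPath path to the counts CSV / MTX file.
#' @param clustersPath path to the two-column cell/cluster TSV.
#' @param genesPath,cellsPath row/column name files for the MTX reader.
#' @return a `SingleCellExperiment` (see [countsWithClusters()]).
#' @export
readCountsCSV <- function(countsPath, clustersPath) {
  df <- utils::read.csv(countsPath, check.names = FALSE,
                        stringsAsFactors = FALSE)
  cells <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- cells
  countsWithClusters(m, readClusterTable(clustersPath, cells))
}

#' @rdname readCountsCSV
#' @export
readCountsMTX <- function(countsPath, genesPath, cellsPath, clustersPath) {
  m <- as.matrix(Matrix::readMM(countsPath))
  rownames(m) <- readLines(genesPath, warn = FALSE)
  cells <- readLines(cellsPath, warn = FALSE)
  colnames(m) <- cells
  countsWithClusters(m, readClusterTable(clustersPath, cells))
}

readClusterTable <- function(path, cells) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = "character")
  if (nrow(df) && normalizeLabel(df[1, 1]) %in% c("cell", "cell id", "barcode"))
    df <- df[-1, , drop = FALSE]
  cl <- stats::setNames(df[[2]], df[[1]])
  missing <- setdiff(cells, names(cl))
  if (length(missing))
    stop("no cluster assignment for cell(s): ",
         paste(head(missing, 5), collapse = ", "))
  unname(cl[cells])
}

# ---- differential expression ---------------------------------------------

# CP10K + log1p normalization; cells with zero totals stay all-zero.
logNormalize <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  log1p(t(t(as.matrix(counts)) / tot) * 1e4)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Midranks for ties; exact p by enumeration of all group assignments when
#' `choose(n, n1)` is at most `maxExact` (so small inputs agree with an
#' exhaustive permutation test even under ties, which
#' `stats::wilcox.test`'s exact path cannot handle), otherwise a
#' tie-corrected normal approximation. Degenerate inputs (all values
#' identical) give p = 1.
#'
#' @param x numeric vector of values for all cells.
#' @param inGroup logical vector, TRUE for cells in the test group.
#' @param maxExact enumeration budget (number of combinations).
#' @return p-value in (0, 1].
#' @export
rankSumP <- function(x, inGroup, maxExact = 20000) {
  n <- length(x)
  n1 <- sum(inGroup)
  n2 <- n - n1
  if (n1 < 1L || n2 < 1L) stop("both groups must be nonempty")
  r <- rank(x)
  W <- sum(r[inGroup])
  mu <- n1 * (n + 1) / 2
  if (choose(n, n1) <= maxExact) {
    combs <- combn(n, n1)
    dist <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(dist - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieAdj)
  if (sigma2 <= 0) return(1)
  min(1, 2 * pnorm(-abs(W - mu) / sqrt(sigma2)))
}

#' Rank one cluster's marker genes (one-vs-rest Wilcoxon)
#'
#' Tests every gene one-vs-rest on log1p CP10K-normalized counts,
#' Benjamini-Hochberg-adjusts across genes, keeps genes over-expressed in
#' the cluster (log2 fold change >= 0 — a marker is a gene the cluster
#' expresses, so significantly depleted genes are not markers), and
#' returns the top `topN` ranked by (adjusted p ascending, |log2FC|
#' descending, symbol ascending). The fold change uses a pseudocount of 1
#' on mean CP10K expression.
#'
#' @param data a `SingleCellExperiment` from [countsWithClusters()].
#' @param cluster cluster id to test (must have >= 2 cells, as must its
#'   complement).
#' @param topN number of top genes to keep (default 20); values above the
#'   gene count are truncated with a warning.
#' @return data.frame with columns gene, log2_fold_change, p_value,
#'   adjusted_p, rank; the cluster id is attached as attribute
#'   `cluster_id`.
#' @export
rankMarkers <- function(data, cluster, topN = 20) {
  cl <- clusterIds(data)
  if (!cluster %in% cl) stop("unknown cluster: ", cluster)
  if (length(unique(cl)) < 2L)
    stop("need at least 2 clusters for differential expression")
  inGroup <- cl == cluster
  if (sum(inGroup) < 2L)
    stop("cluster '", cluster, "' has fewer than 2 cells")
  if (sum(!inGroup) < 2L)
    stop("complement of cluster '", cluster, "' has fewer than 2 cells")
  ln <- logNormalize(SummarizedExperiment::assay(data, "counts"))
  cp10k <- expm1(ln)
  genes <- rownames(data)
  p <- vapply(seq_along(genes),
              function(i) rankSumP(ln[i, ], inGroup), numeric(1))
  lfc <- log2((rowMeans(cp10k[, inGroup, drop = FALSE]) + 1) /
              (rowMeans(cp10k[, !inGroup, drop = FALSE]) + 1))
  adj <- p.adjust(p, method = "BH")
  res <- data.frame(gene = genes, log2_fold_change = lfc, p_value = p,
                    adjusted_p = adj, stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- res[res$log2_fold_change >= 0, , drop = FALSE]
  res <- res[orderC(res$adjusted_p, -abs(res$log2_fold_change), res$gene), ,
             drop = FALSE]
  if (topN > length(genes)) {
    warning("topN (", topN, ") exceeds the gene count (", length(genes),
            "); truncating")
    topN <- length(genes)
  }
  res <- head(res, topN)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "cluster_id") <- as.character(cluster)
  res
}

# ---- gene sets and over-representation -----------------------------------

#' Read a GMT gene-set collection
#'
#' Standard GMT: tab-separated name, description, then gene symbols.
#' Lines starting with `#` are skipped; set names must be unique and sets
#' nonempty.
#'
#' @param path GMT file path.
#' @return named list of upper-cased gene-symbol vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    genes <- normalizeGenes(parts[-(1:2)])
    if (!length(genes)) stop("empty gene set: ", parts[1])
    if (parts[1] %in% names(sets)) stop("duplicate set name: ", parts[1])
    sets[[parts[1]]] <- sortC(unique(genes))
  }
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each set in the collection, tests the overlap with the query
#' against the universe with the upper-tail hypergeometric probability
#' P(X >= overlap), then Benjamini-Hochberg-adjusts across the tested
#' terms. Sets are intersected with the universe first; a set with empty
#' intersection is skipped (with a message). Results are sorted by
#' adjusted p, then term name.
#'
#' @param query character vector of gene symbols (must be a subset of the
#'   universe and nonempty).
#' @param collection named list of gene sets (see [readGMT()]).
#' @param universe character vector of background gene symbols.
#' @return data.frame with columns term, overlap_count, set_size,
#'   query_size, universe_size, p_value, adjusted_p.
#' @examples
#' uni <- paste0("G", 1:20)
#' ora <- oraEnrich(uni[1:5], list(hit = uni[1:5]), uni)
#' ora$p_value  # 1 / choose(20, 5)
#' @export
oraEnrich <- function(query, collection, universe) {
  query <- unique(normalizeGenes(query))
  universe <- unique(normalizeGenes(universe))
  if (!length(query)) stop("query gene set is empty")
  if (!length(universe)) stop("universe gene set is empty")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query genes missing from the universe: ",
         paste(head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- list()
  for (term in names(collection)) {
    set <- intersect(unique(normalizeGenes(collection[[term]])), universe)
    if (!length(set)) {
      message("ORA: term '", term, "' has no genes in the universe; skipped")
      next
    }
    k <- length(intersect(set, query))
    K <- length(set)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[term]] <- data.frame(term = term, overlap_count = k, set_size = K,
                               query_size = n, universe_size = N,
                               p_value = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(0), overlap_count = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0)))
  res <- do.call(rbind, rows)
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res <- res[orderC(res$adjusted_p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- evidence assembly ----------------------------------------------------

#' Evidence bundle for a single cluster
#'
#' Ranked top markers plus (when a collection is given) ORA of those
#' markers against the matrix-wide gene universe, bundled with the shared
#' biological context.
#'
#' @param data a `SingleCellExperiment` from [countsWithClusters()].
#' @param cluster cluster id.
#' @param collection named list of gene sets, or NULL to skip enrichment
#'   (downstream scoring then uses the two-component rubric).
#' @param context a [BiologicalContext-class].
#' @param topN number of top marker genes (default 20).
#' @param sigCut adjusted-p significance cut for enriched terms (default
#'   0.05).
#' @param universe background gene set for ORA; default all genes in the
#'   matrix.
#' @return a [ClusterEvidence-class].
#' @export
clusterEvidenceFor <- function(data, cluster, collection = NULL,
                               context = biologicalContext(), topN = 20,
                               sigCut = 0.05, universe = rownames(data)) {
  mk <- rankMarkers(data, cluster, topN = topN)
  enr <- NULL
  if (!is.null(collection) && nrow(mk))
    enr <- oraEnrich(mk$gene, collection, universe)
  clusterEvidence(cluster, mk, enrichment = enr, context = context,
                  sigCut = sigCut)
}

#' Extract evidence bundles for every cluster
#'
#' @inheritParams clusterEvidenceFor
#' @return named list of [ClusterEvidence-class], one per cluster, ordered
#'   by cluster id.
#' @export
extractEvidence <- function(data, collection = NULL,
                            context = biologicalContext(), topN = 20,
                            sigCut = 0.05) {
  clusters <- sortC(unique(clusterIds(data)))
  out <- lapply(clusters, function(cl)
    clusterEvidenceFor(data, cl, collection = collection, context = context,
                       topN = topN, sigCut = sigCut))
  stats::setNames(out, clusters)
}
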