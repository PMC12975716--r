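test_that("a perfect separator gene ranks first with positive log2FC", {
  mk <- rankMarkers(toyCounts(), "A", topN = 3)
  expect_identical(mk$gene[1], "G1")
  expect_gt(mk$log2_fold_change[1], 0)
  expect_identical(mk$rank, seq_len(nrow(mk)))
  expect_true(all(mk$adjusted_p >= mk$p_value))
})

test_that("identical genes give p = 1 and fall back to symbol order", {
  counts <- matrix(2L, nrow = 3, ncol = 6,
                   dimnames = list(c("GB", "GC", "GA"), paste0("c", 1:6)))
  data <- countsWithClusters(counts, rep(c("A", "B"), each = 3))
  mk <- rankMarkers(data, "A", topN = 3)
  expect_true(all(mk$adjusted_p == 1))
  expect_identical(mk$gene, c("GA", "GB", "GC"))
})

test_that("small-sample Wilcoxon p equals exhaustive permutation-test p", {
  # independent oracle: enumerate every assignment of the group labels,
  # recompute the rank-sum from scratch, and count assignments at least
  # as extreme as the observed one
  permutationOracle <- function(x, inGroup) {
    n <- length(x); n1 <- sum(inGroup)
    r <- rank(x)
    obs <- abs(sum(r[inGroup]) - n1 * (n + 1) / 2)
    hits <- 0; total <- 0
    for (idx in asplit(combn(n, n1), 2)) {
      stat <- abs(sum(r[idx]) - n1 * (n + 1) / 2)
      hits <- hits + (stat >= obs - 1e-9)
      total <- total + 1
    }
    hits / total
  }
  set.seed(7)
  for (rep in 1:20) {
    x <- as.numeric(sample(0:4, 8, replace = TRUE))   # heavy ties
    grp <- seq_len(8) %in% sample(8, 4)
    expect_equal(rankSumP(x, grp), permutationOracle(x, grp),
                 tolerance = 1e-12)
  }
  # and through the full rankMarkers path on an 8-cell toy matrix
  set.seed(8)
  counts <- matrix(rpois(4 * 8, 3), nrow = 4,
                   dimnames = list(paste0("G", 1:4), paste0("c", 1:8)))
  data <- countsWithClusters(counts, rep(c("A", "B"), each = 4))
  ln <- log1p(t(t(counts) / colSums(counts)) * 1e4)
  mk <- rankMarkers(data, "A", topN = 4)
  for (i in seq_len(nrow(mk))) {
    g <- mk$gene[i]
    expect_equal(mk$p_value[i],
                 permutationOracle(ln[g, ], rep(c(TRUE, FALSE), each = 4)),
                 tolerance = 1e-12)
  }
})

test_that("rankMarkers validates inputs and truncates oversized topN", {
  data <- toyCounts()
  expect_error(rankMarkers(data, "Z"), "unknown cluster")
  tiny <- countsWithClusters(
    matrix(1:6, nrow = 2, dimnames = list(c("G1", "G2"), paste0("c", 1:3))),
    c("A", "B", "B"))
  expect_error(rankMarkers(tiny, "A"), "fewer than 2 cells")
  expect_warning(mk <- rankMarkers(data, "A", topN = 10), "truncat")
  expect_lte(nrow(mk), 3)
})

test_that("rankMarkers is invariant to cell-column permutation", {
  set.seed(11)
  counts <- matrix(rnbinom(20 * 30, size = 2, mu = 3), nrow = 20,
                   dimnames = list(sprintf("G%02d", 1:20),
                                   sprintf("c%02d", 1:30)))
  cl <- rep(c("A", "B", "C"), each = 10)
  data <- countsWithClusters(counts, cl)
  perm <- sample(30)
  dataP <- countsWithClusters(counts[, perm], cl[perm])
  for (cluster in c("A", "B")) {
    a <- rankMarkers(data, cluster, topN = 10)
    b <- rankMarkers(dataP, cluster, topN = 10)
    expect_identical(a$gene, b$gene)
    expect_equal(a, b)
  }
})

test_that("ORA p-values match the closed form and enumeration oracles", {
  uni <- paste0("G", sprintf("%02d", 1:20))
  res <- oraEnrich(uni[1:5], list(hit = uni[1:5]), uni)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # disjoint term: P(X >= 0) = 1
  res0 <- oraEnrich(uni[1:5], list(miss = uni[6:10]), uni)
  expect_identical(res0$overlap_count, 0L)
  expect_equal(res0$p_value, 1.0)

  # enumeration oracle on universes <= 15 genes: draw every possible
  # query of size n and count overlaps at least as large as observed
  enumOracle <- function(set, query, universe) {
    k <- length(intersect(set, query))
    draws <- combn(length(universe), length(query))
    mean(apply(draws, 2, function(idx)
      length(intersect(universe[idx], set)) >= k))
  }
  set.seed(13)
  for (rep in 1:10) {
    N <- sample(8:15, 1)
    universe <- paste0("G", seq_len(N))
    set <- sample(universe, sample(2:N, 1))
    query <- sample(universe, sample(2:6, 1))
    res <- suppressMessages(
      oraEnrich(query, list(s = set), universe))
    expect_equal(res$p_value, enumOracle(set, query, universe),
                 tolerance = 1e-12)
  }
})

test_that("ORA validates inputs, skips out-of-universe terms, sorts stably", {
  uni <- paste0("G", 1:10)
  expect_error(oraEnrich(character(0), list(a = uni[1:2]), uni), "empty")
  expect_error(oraEnrich(uni[1:2], list(a = uni[1:2]), character(0)),
               "empty")
  expect_error(oraEnrich(c("G1", "NOPE"), list(a = uni[1:2]), uni),
               "missing from the universe")
  expect_message(
    res <- oraEnrich(uni[1:3], list(a = uni[1:3], ghost = "ZZZ"), uni),
    "skipped")
  expect_identical(res$term, "a")
  # BH monotonicity: order by p equals order by adjusted p (up to ties)
  set.seed(17)
  coll <- lapply(1:8, function(i) sample(uni, sample(2:6, 1)))
  names(coll) <- paste0("t", 1:8)
  res <- oraEnrich(uni[1:4], coll, uni)
  expect_false(is.unsorted(res$adjusted_p))
  expect_false(is.unsorted(res$adjusted_p[order(res$p_value)]))
})

test_that("GMT reader parses sets and rejects malformed input", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tCD19\tMS4A1",
               "setB\t-\tcd3d"), gmt)
  coll <- readGMT(gmt)
  expect_identical(coll$setA, c("CD19", "MS4A1"))
  expect_identical(coll$setB, "CD3D")
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely\tdesc", bad)
  expect_error(readGMT(bad), "malformed")
})

test_that("extractEvidence bundles markers, enrichment, and context", {
  kb <- markerKnowledgeBase(
    markerEntry("B cell", broadMarkers = c("CD19", "MS4A1")),
    markerEntry("T cell", broadMarkers = c("CD3D", "CD3E")))
  sim <- generateSynthData(synthSpec(kb, cellsPerCluster = 15,
                                     nBackgroundGenes = 20, seed = 5))
  coll <- list(bcr = c("CD19", "MS4A1"), tcr = c("CD3D", "CD3E"))
  ctx <- biologicalContext(tissue = "blood")
  ev <- extractEvidence(sim$data, coll, context = ctx, topN = 5)
  expect_named(ev, c("C1", "C2"))
  for (e in ev) {
    expect_s4_class(e, "ClusterEvidence")
    expect_lte(length(topGenes(e)), 5)
    expect_s4_class(e@context, "BiologicalContext")
    expect_true(is.data.frame(e@enrichment))
  }
  # determinism: identical call gives identical bundles
  ev2 <- extractEvidence(sim$data, coll, context = ctx, topN = 5)
  expect_identical(lapply(ev, function(e) e@markers),
                   lapply(ev2, function(e) e@markers))
  # omitting the collection yields empty enrichment (two-component path)
  evNo <- extractEvidence(sim$data, NULL, context = ctx, topN = 5)
  expect_null(evNo$C1@enrichment)
})

test_that("CSV and MTX readers reconstruct the same container", {
  sim <- generateSynthData(synthSpec(markerKnowledgeBase(
    markerEntry("B cell", broadMarkers = "CD19"),
    markerEntry("T cell", broadMarkers = "CD3D")),
    cellsPerCluster = 4, nBackgroundGenes = 3, seed = 2))
  dir <- withr::local_tempdir()
  paths <- writeSynthData(sim, dir)
  data <- readCountsCSV(paths["counts"], paths["clusters"])
  expect_identical(dim(data), dim(sim$data))
  expect_identical(clusterIds(data), clusterIds(sim$data))
  expect_equal(
    as.matrix(SummarizedExperiment::assay(data)),
    as.matrix(SummarizedExperiment::assay(sim$data)))

  m <- SummarizedExperiment::assay(sim$data)
  mtx <- file.path(dir, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE), mtx)
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "cells.txt"))
  data2 <- readCountsMTX(mtx, file.path(dir, "genes.txt"),
                         file.path(dir, "cells.txt"), paths["clusters"])
  expect_equal(as.matrix(SummarizedExperiment::assay(data2)),
               as.matrix(SummarizedExperiment::assay(sim$data)))
})
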