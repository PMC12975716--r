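test_that("prospect filters by tissue, orders by name, and truncates", {
  kb <- demoKB()
  blood <- prospect(biologicalContext(tissue = "blood"), kb)
  expect_identical(shortlistNames(blood),
                   c("B cell", "NK cell", "T cell", "monocyte"))
  all <- prospect(biologicalContext(), kb)
  expect_identical(shortlistNames(all), kbNames(kb))
  one <- prospect(biologicalContext(tissue = "blood"), kb, limit = 1)
  expect_identical(shortlistNames(one), "B cell")
  expect_error(prospect(biologicalContext(), markerKnowledgeBase()),
               "empty")
  # unknown tissue: nonempty fallback rather than an empty shortlist
  mars <- prospect(biologicalContext(tissue = "mars"), kb)
  expect_identical(shortlistNames(mars), kbNames(kb))
  expect_match(unname(mars@provenance[1]), "fallback")
})

test_that("insight scores every shortlisted candidate with full breakdowns", {
  kb <- demoKB()
  ctx <- biologicalContext(tissue = "blood")
  sl <- prospect(ctx, kb)
  ev <- makeEvidence(c("CD19", "MS4A1", "CD79A"), context = ctx)
  bds <- insight(sl, ev, ctx, kb)
  expect_length(bds, length(shortlistNames(sl)))
  nm <- vapply(bds, function(b) b@candidate, character(1))
  expect_identical(nm, shortlistNames(sl))
  totals <- vapply(bds, breakdownTotal, numeric(1))
  # the B-cell candidate strictly wins on B-cell evidence
  expect_identical(nm[which.max(totals)], "B cell")
  expect_gt(sort(totals, decreasing = TRUE)[1],
            sort(totals, decreasing = TRUE)[2])
})

test_that("review keeps exactly three slots, ordered, ties by name", {
  kb <- demoKB()
  ctx <- biologicalContext(tissue = "blood")
  ev <- makeEvidence(c("CD19", "MS4A1", "CD79A"), context = ctx)
  sl <- prospect(ctx, kb)
  rec <- reviewCluster(insight(sl, ev, ctx, kb), ev, kb, margin = 15)
  expect_length(rec$candidates, 3)
  totals <- vapply(rec$candidates, function(cand) cand$breakdown$total,
                   numeric(1))
  expect_false(is.unsorted(rev(totals)))
  expect_identical(rec$candidates[[1]]$name, "B cell")
  # equal totals are ordered by name ascending (deterministic)
  bds <- list(scoreCandidate(ev, markerEntry("zeta cell")),
              scoreCandidate(ev, markerEntry("alpha cell")),
              scoreCandidate(ev, markerEntry("mid cell")))
  recTie <- reviewCluster(bds, ev, kb)
  expect_identical(
    vapply(recTie$candidates, function(cand) cand$name, character(1)),
    c("alpha cell", "mid cell", "zeta cell"))
})

test_that("review flags low-agreement clusters by the margin rule", {
  ev <- makeEvidence("CD19")
  mk <- function(nm, pts) new("ScoreBreakdown", candidate = nm,
                              criteria = c(marker_match = pts),
                              items = list(marker_match = "CD19"),
                              markerComponent = pts,
                              pathwayComponent = numeric(0),
                              contextComponent = 0, total = pts)
  kb <- demoKB()
  recClose <- reviewCluster(list(mk("A", 50), mk("B", 48)), ev, kb,
                            margin = 5)
  expect_true(recClose$flagged)
  recFar <- reviewCluster(list(mk("A", 80), mk("B", 40), mk("C", 10),
                               mk("D", 5)), ev, kb, margin = 15)
  expect_false(recFar$flagged)
  expect_equal(vapply(recFar$candidates,
                      function(cand) cand$breakdown$total, numeric(1)),
               c(80, 40, 10))
})

test_that("review marks absent slots explicitly for a tiny knowledge base", {
  kb <- markerKnowledgeBase(markerEntry("B cell", broadMarkers = "CD19"))
  ctx <- biologicalContext()
  ev <- makeEvidence("CD19", context = ctx)
  rec <- reviewCluster(insight(prospect(ctx, kb), ev, ctx, kb), ev, kb)
  expect_length(rec$candidates, 3)
  expect_false(isTRUE(rec$candidates[[1]]$absent))
  expect_true(rec$candidates[[2]]$absent)
  expect_true(rec$candidates[[3]]$absent)
})

test_that("candidates carry key markers and gold-standard validation markers", {
  kb <- demoKB()
  ctx <- biologicalContext(tissue = "blood")
  ev <- makeEvidence(c("CD19", "MS4A1"), context = ctx)
  rec <- reviewCluster(insight(prospect(ctx, kb), ev, ctx, kb), ev, kb)
  top <- rec$candidates[[1]]
  expect_identical(top$name, "B cell")
  expect_setequal(top$key_markers, c("CD19", "MS4A1"))
  # validation markers: KB positives not already in the top DEGs
  expect_setequal(top$validation_markers, c("CD79A", "TCL1A"))
  expect_match(top$reasoning, "broad markers")
})

test_that("standardize harmonizes synonym variants and keeps the unknown", {
  kb <- demoKB()
  expect_identical(
    unname(standardizeLabels(c("B cells", "B-cell"), kb)),
    c("B cell", "B cell"))
  expect_identical(unname(standardizeLabels("T cell", kb)), "T cell")
  expect_warning(
    out <- standardizeLabels(c("B cells", "mystery cell"), kb),
    "mystery cell")
  expect_identical(unname(out), c("B cell", "mystery cell"))
})

test_that("replay backend reproduces recordings and fails loudly on miss", {
  kb <- demoKB()
  ctx <- biologicalContext(tissue = "blood")
  sl <- prospect(ctx, kb)
  ev1 <- makeEvidence(c("CD19", "MS4A1"), context = ctx, clusterId = "C1")
  ev2 <- makeEvidence(c("CD3D", "CD2"), context = ctx, clusterId = "C2")
  rec <- withr::local_tempfile(fileext = ".json")
  recordReplayFixture(rec, sl, list(ev1, ev2), ctx, kb)
  rb <- replayBackend(rec)
  expect_true(rb@deterministic)
  entries <- lapply(shortlistNames(sl), kbEntry, kb = kb)
  live <- rubricBackend()@scoreFun(entries, ev1, ctx, rubricConfig())
  replayed <- rb@scoreFun(entries, ev1, ctx, rubricConfig())
  expect_identical(lapply(replayed, scRubric:::breakdownToList),
                   lapply(live, scRubric:::breakdownToList))
  # unseen request -> hard error, never a silent fallback
  evMiss <- makeEvidence("GNLY", context = ctx, clusterId = "C9")
  expect_error(rb@scoreFun(entries, evMiss, ctx, rubricConfig()),
               "cache miss")
})

test_that("annotateAll recovers a planted signature end to end", {
  kb <- bloodKB5()
  sim <- generateSynthData(synthSpec(kb, seed = 101))
  pipe <- annotateAll(sim$data, kb,
                      context = biologicalContext(tissue = "blood"))
  for (cl in names(pipe$clusters)) {
    rec <- pipe$clusters[[cl]]
    expect_null(rec$error)
    expect_identical(rec$candidates[[1]]$name, sim$truth[[cl]])
  }
})

test_that("annotation is order-independent, deterministic, and isolates failures", {
  kb <- bloodKB5()
  sim <- generateSynthData(synthSpec(kb, cellsPerCluster = 20,
                                     nBackgroundGenes = 30, seed = 55))
  ctx <- biologicalContext(tissue = "blood")
  serial <- annotateAll(sim$data, kb, context = ctx, workers = 1)
  concurrent <- annotateAll(sim$data, kb, context = ctx, workers = 2)
  expect_identical(serial, concurrent)
  # identical runs are byte-identical through the report serialization
  r1 <- buildReport(serial, seed = 55, timestamp = "t")
  r2 <- buildReport(concurrent, seed = 55, timestamp = "t")
  expect_identical(reportToJSON(r1), reportToJSON(r2))

  # a 1-cell cluster fails alone; every other cluster is still annotated
  counts <- SummarizedExperiment::assay(sim$data)
  lone <- matrix(1L, nrow = nrow(counts), ncol = 1,
                 dimnames = list(rownames(counts), "lonely"))
  broken <- countsWithClusters(cbind(counts, lone),
                               c(clusterIds(sim$data), "C9"))
  pipe <- annotateAll(broken, kb, context = ctx)
  expect_match(pipe$clusters$C9$error, "fewer than 2 cells")
  for (cl in setdiff(names(pipe$clusters), "C9"))
    expect_null(pipe$clusters[[cl]]$error)
})
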