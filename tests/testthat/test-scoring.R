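bcell <- function() kbEntry(demoKB(), "B cell")
tcell <- function() kbEntry(demoKB(), "T cell")

test_that("marker profile awards the configured caps and deductions", {
  cfg <- rubricConfig()
  # all broad markers present, nothing else -> full +45
  ev <- makeEvidence(c("CD19", "MS4A1", "CD79A"))
  mk <- scoreMarkerProfile(ev, bcell(), config = cfg)
  expect_equal(unname(mk$points["marker_match"]), 45)
  expect_equal(sum(mk$points), 45)
  # all narrow markers, no broad -> +15
  mkN <- scoreMarkerProfile(makeEvidence("TCL1A"), bcell(), config = cfg)
  expect_equal(unname(mkN$points["narrow_marker"]), 15)
  expect_equal(sum(mkN$points), 15)
  # empty topDEG -> all zero
  mk0 <- scoreMarkerProfile(makeEvidence(character(0)), bcell(),
                            config = cfg)
  expect_equal(sum(mk0$points), 0)
  # only a negative marker present -> -30
  mkNeg <- scoreMarkerProfile(makeEvidence("CD3D"), bcell(), config = cfg)
  expect_equal(unname(mkNeg$points["negative_marker"]), -30)
  expect_equal(sum(mkNeg$points), -30)
})

test_that("partial broad match gets proportional credit rounded half-up", {
  entry <- markerEntry("X", broadMarkers = c("A1", "A2", "A3", "A4"))
  mk <- scoreMarkerProfile(makeEvidence(c("A1", "A2")), entry)
  expect_equal(unname(mk$points["marker_match"]), 23)  # 45 * 2/4 = 22.5
  mk1 <- scoreMarkerProfile(makeEvidence("A1"), entry)
  expect_equal(unname(mk1$points["marker_match"]), 11)  # 45 / 4 = 11.25
})

test_that("shared-marker deduction fires once against shortlist competitors", {
  entry <- markerEntry("X", broadMarkers = c("A1", "A2"))
  rival <- markerEntry("Y", broadMarkers = c("A1", "B1"))
  mk <- scoreMarkerProfile(makeEvidence(c("A1", "A2")), entry,
                           shortlist = list(rival))
  expect_equal(unname(mk$points["marker_match"]), 45)
  expect_equal(unname(mk$points["shared_marker"]), -10)
  expect_identical(mk$items$shared_marker, "A1")
  # several shared markers still deduct only once
  rival2 <- markerEntry("Z", broadMarkers = c("A1", "A2"))
  mk2 <- scoreMarkerProfile(makeEvidence(c("A1", "A2")), entry,
                            shortlist = list(rival, rival2))
  expect_equal(unname(mk2$points["shared_marker"]), -10)
})

test_that("pathway profile scores states, types, sharing, and conflicts", {
  cfg <- rubricConfig()
  entry <- bcell()   # state: interferon response; type: BCR signaling
  # all state pathways matched -> +15
  ev <- makeEvidence("CD19", makeEnrichment("interferon response"))
  pw <- scorePathwayProfile(ev, entry, config = cfg)
  expect_equal(unname(pw$points["pathway_state"]), 15)
  expect_equal(unname(pw$points["pathway_type"]), 0)
  # type pathway matched -> +5
  evT <- makeEvidence("CD19", makeEnrichment("B cell receptor signaling"))
  pwT <- scorePathwayProfile(evT, entry, config = cfg)
  expect_equal(unname(pwT$points["pathway_type"]), 5)
  # no enrichment supplied -> operation skipped entirely
  expect_null(scorePathwayProfile(makeEvidence("CD19"), entry,
                                  config = cfg))
  # a significant term exclusive to a competitor -> conflict -20
  evC <- makeEvidence("CD19", makeEnrichment("T cell receptor signaling"))
  pwC <- scorePathwayProfile(evC, entry, shortlist = list(tcell()),
                             config = cfg)
  expect_equal(unname(pwC$points["pathway_conflict"]), -20)
  expect_equal(sum(pwC$points), -20)
  # a matched pathway shared with a competitor -> shared -10, no conflict
  shared <- markerEntry("Y", pathwaysState = "interferon response")
  pwS <- scorePathwayProfile(ev, entry, shortlist = list(shared),
                             config = cfg)
  expect_equal(unname(pwS$points["pathway_shared"]), -10)
  expect_equal(unname(pwS$points["pathway_conflict"]), 0)
  # non-significant terms never score
  evNS <- makeEvidence("CD19", makeEnrichment(character(0),
                                              ns = "interferon response"))
  pwNS <- scorePathwayProfile(evNS, entry, config = cfg)
  expect_equal(sum(pwNS$points), 0)
})

test_that("context scoring: plausibility, vacuous context, implausibility", {
  cfg <- rubricConfig()
  blood <- biologicalContext(tissue = "blood")
  cx <- scoreContext(bcell(), blood, cfg)
  expect_equal(unname(cx$points["context_type"]), 10)
  # empty context: vacuous plausibility, no state points
  cx0 <- scoreContext(bcell(), biologicalContext(), cfg)
  expect_equal(unname(cx0$points["context_type"]), 10)
  expect_equal(unname(cx0$points["context_state"]), 0)
  expect_equal(sum(cx0$points), 10)
  # liver context for a blood-only entry -> -30 and no type points
  liver <- biologicalContext(tissue = "liver")
  cxL <- scoreContext(bcell(), liver, cfg)
  expect_equal(unname(cxL$points["context_implausible"]), -30)
  expect_equal(sum(cxL$points), -30)
  # matching tissue+condition awards the state points too
  inflamed <- biologicalContext(tissue = "blood",
                                condition = "inflammation")
  cxS <- scoreContext(bcell(), inflamed, cfg)
  expect_equal(unname(cxS$points["context_state"]), 10)
})

test_that("scoreCandidate composes components; totals hit the stated sums", {
  cfg <- rubricConfig()
  entry <- bcell()
  # evidence maxing every positive criterion, no deductions -> 100
  evMax <- makeEvidence(
    c("CD19", "MS4A1", "CD79A", "TCL1A"),
    makeEnrichment(c("interferon response", "B cell receptor signaling")),
    context = biologicalContext(tissue = "blood",
                                condition = "inflammation"))
  bd <- scoreCandidate(evMax, entry, config = cfg)
  expect_equal(breakdownTotal(bd), 100)
  expect_equal(bd@markerComponent, 60)
  expect_equal(bd@pathwayComponent, 20)
  expect_equal(bd@contextComponent, 20)
  # empty evidence, empty context -> vacuous context type only
  bd0 <- scoreCandidate(makeEvidence(character(0)), entry, config = cfg)
  expect_equal(breakdownTotal(bd0), 10)
  # two-component path: no pathway component, no pathway criteria;
  # full marker match + plausible tissue and state -> 45 + 10 + 10
  bd2 <- scoreCandidate(
    makeEvidence(c("CD19", "MS4A1", "CD79A"),
                 context = biologicalContext(tissue = "blood")),
    entry, config = cfg)
  expect_length(bd2@pathwayComponent, 0)
  expect_false(any(grepl("pathway", names(bd2@criteria))))
  expect_equal(breakdownTotal(bd2), 65)
})

test_that("breakdowns conserve points and respect the rubric bounds", {
  cfg <- rubricConfig()
  kb <- demoKB()
  set.seed(23)
  genePool <- c(unlist(lapply(kb@entries, function(e)
    c(e@broadMarkers, e@narrowMarkers, e@negativeMarkers))),
    sprintf("GBG%02d", 1:10))
  termPool <- unlist(lapply(kb@entries, function(e)
    c(e@pathwaysType, e@pathwaysState)))
  for (i in 1:50) {
    genes <- sample(genePool, sample(0:12, 1))
    enr <- if (runif(1) < 0.5) NULL
           else makeEnrichment(sample(termPool, sample(0:2, 1)))
    ctx <- biologicalContext(
      tissue = sample(c("", "blood", "liver"), 1),
      condition = sample(c("", "inflammation"), 1))
    nm <- sample(kbNames(kb), 1)
    others <- lapply(setdiff(kbNames(kb), nm), kbEntry, kb = kb)
    bd <- scoreCandidate(makeEvidence(genes, enr, ctx), kbEntry(kb, nm),
                         shortlist = others, config = cfg)
    expect_equal(breakdownTotal(bd), sum(bd@criteria))
    expect_gte(breakdownTotal(bd), -100)
    expect_lte(breakdownTotal(bd), 100)
    caps <- c(marker_match = 45, narrow_marker = 15, shared_marker = 0,
              negative_marker = 0, pathway_state = 15, pathway_type = 5,
              pathway_shared = 0, pathway_conflict = 0, context_type = 10,
              context_state = 10, context_implausible = 0)
    floors <- c(marker_match = 0, narrow_marker = 0, shared_marker = -10,
                negative_marker = -30, pathway_state = 0, pathway_type = 0,
                pathway_shared = -10, pathway_conflict = -20,
                context_type = 0, context_state = 0,
                context_implausible = -30)
    for (crit in names(bd@criteria)) {
      expect_lte(bd@criteria[[crit]], caps[[crit]])
      expect_gte(bd@criteria[[crit]], floors[[crit]])
    }
  }
})

test_that("scoring is monotone in evidence and a pure function", {
  cfg <- rubricConfig()
  entry <- bcell()
  ctx <- biologicalContext(tissue = "blood")
  base <- c("CD19", "GBG01")
  bd <- scoreCandidate(makeEvidence(base, context = ctx), entry,
                       config = cfg)
  # adding a matched broad marker never decreases the total
  bdUp <- scoreCandidate(makeEvidence(c(base, "MS4A1"), context = ctx),
                         entry, config = cfg)
  expect_gte(breakdownTotal(bdUp), breakdownTotal(bd))
  # adding a negative marker never increases it
  bdNeg <- scoreCandidate(makeEvidence(c(base, "CD3D"), context = ctx),
                          entry, config = cfg)
  expect_lte(breakdownTotal(bdNeg), breakdownTotal(bd))
  # purity: identical inputs give identical breakdowns
  expect_identical(
    scoreCandidate(makeEvidence(base, context = ctx), entry, config = cfg),
    bd)
})

test_that("custom rubric configurations propagate and are validated", {
  cfg <- rubricConfig(markerMatchMax = 50, negativeMarkerDeduction = -40)
  mk <- scoreMarkerProfile(makeEvidence(c("CD19", "MS4A1", "CD79A")),
                           bcell(), config = cfg)
  expect_equal(unname(mk$points["marker_match"]), 50)
  expect_error(rubricConfig(markerMatchMax = -5), "maxima")
  expect_error(rubricConfig(sharedMarkerDeduction = 3), "deductions")
  expect_error(rubricConfig(bogusField = 1), "unknown rubric field")
})
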