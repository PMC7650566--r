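test_that("the default design expands to 33 individuals and 165 records", {
  slots <- buildDesign(studyDesign())
  expect_equal(length(unique(slots$individual)), 33L)
  expect_equal(nrow(slots), 165L)
  expect_equal(unique(table(slots$individual)), 5L)

  small <- studyDesign(cells = data.frame(code = "YFT",
                                          species = "Thunnus albacares",
                                          area = "IO"),
                       individualsPerCell = 1L)
  expect_equal(nrow(buildDesign(small)), 5L)
  expect_error(studyDesign(levels = character()), "start with L1")
  expect_error(studyDesign(individualsPerCell = 0L), "at least one")
})

test_that("degradation parameter invariants are enforced", {
  expect_error(degradationParams(lambda = c(L1 = 1, L2 = 2)), "L1")
  expect_error(degradationParams(lambda = c(L1 = 0, L2 = -1)), "non-negative")
  expect_error(degradationParams(amplification = list(L1 = c(AB = 0.5))),
               "sum to 1")
  expect_error(degradationParams(diagnosticBias = 1.5), "\\[0, 1\\]")
})

test_that("applyDegradation honours rate, bias and determinism", {
  s <- strsplit(randomSeq(100), "")[[1]]
  none <- applyDegradation(s, lambda = 0)
  expect_identical(none$sequence, s)
  expect_length(none$columns, 0L)

  diag <- c(5L, 17L, 40L, 66L, 80L, 91L, 99L)
  set.seed(3)
  hits <- replicate(30, {
    r <- applyDegradation(s, lambda = 5, diagnosticBias = 1,
                          diagnosticColumns = diag)
    expect_true(all(r$columns %in% diag))
    length(r$columns)
  })
  expect_true(any(hits > 0))

  set.seed(77); a <- applyDegradation(s, 4, 0.5, diag)
  set.seed(77); b <- applyDegradation(s, 4, 0.5, diag)
  expect_identical(a, b)
  # substituted columns really differ from the input
  expect_true(all(a$sequence[match(a$columns, seq_along(s))] !=
                    s[match(a$columns, seq_along(s))]))
})

test_that("synthesized panels realize the planted distance structure", {
  for (seed in c(1, 2, 3)) {
    syn <- synthesizePanel(panelSpec(seed = seed))
    expect_length(validatePanel(syn$panel), 0L)
    tab <- distanceTable(syn$panel)
    intra <- tab$dist[tab$class == "intra"]
    inter <- tab$dist[tab$class == "inter"]
    expect_true(all(intra >= 0 & intra <= 0.05))
    expect_true(all(inter >= 0.09 & inter <= 0.14))
    # planted diagnostics are recovered exactly by the independent scan
    for (sp in unique(panelSpecies(syn$panel)))
      expect_identical(bruteDiagnostics(syn$panel, sp),
                       as.integer(syn$diagnostics[[sp]]))
    # at least 7 diagnostics inside fragment B
    for (sp in unique(panelSpecies(syn$panel)))
      expect_gte(length(diagnosticPositions(syn$panel, sp, fragment = "B")), 7L)
  }
})

test_that("one sequence per species is a valid degenerate panel", {
  syn <- synthesizePanel(panelSpec(seqsPerSpecies = 1L, seed = 4))
  tab <- distanceTable(syn$panel)
  expect_equal(sum(tab$class == "intra"), 0L)
  expect_true(all(tab$dist >= 0.09 & tab$dist <= 0.14))
})

test_that("infeasible panel specs fail fast", {
  expect_error(panelSpec(intraRange = c(0, 0.1), interRange = c(0.09, 0.14)),
               "strictly below")
  expect_error(synthesizePanel(panelSpec(alignmentLength = 40L, seed = 1)),
               "feasibility error")
})

test_that("simulated studies honour the count and cumulativeness contracts", {
  syn <- synthesizePanel(panelSpec(seed = 6))
  study <- simulateStudy(studyDesign(), syn$panel, degradationParams(),
                         syn$diagnostics, seed = 16)
  expect_equal(nrow(study), 165L)
  expect_equal(length(unique(study$individual)), 33L)

  # degradation never reverts: substitution sets grow along levels (within
  # the columns still observable at the later level)
  lv <- c("L1", "L2", "L3", "L4O", "L4B")
  subsOf <- function(x) if (!nzchar(x)) integer() else
    as.integer(strsplit(x, ",")[[1]])
  frB <- 128:236
  for (ind in unique(study$individual)) {
    rows <- study[study$individual == ind, ]
    prev <- integer()
    for (l in lv) {
      r <- rows[rows$level == l, ]
      if (r$fragment == "FAIL") next
      cur <- subsOf(r$truth_subs)
      cols <- if (r$fragment == "B") frB else if (r$fragment == "A") 1:117
              else 1:236
      expect_true(all(cur %in% cols))
      expect_true(all(intersect(prev, cols) %in% cur))
      prev <- union(prev, cur)
    }
  }

  # determinism: same seed, same study
  again <- simulateStudy(studyDesign(), syn$panel, degradationParams(),
                         syn$diagnostics, seed = 16)
  expect_identical(study, again)
})

test_that("forcing AB amplification yields AB everywhere", {
  syn <- synthesizePanel(panelSpec(seed = 9))
  params <- degradationParams(amplification = list(
    L1 = c(AB = 1), L2 = c(AB = 1), L3 = c(AB = 1),
    L4O = c(AB = 1), L4B = c(AB = 1)))
  study <- simulateStudy(studyDesign(), syn$panel, params, syn$diagnostics,
                         seed = 2)
  expect_true(all(study$fragment == "AB"))
  expect_true(all(!is.na(study$sequence)))
})

test_that("an undegraded study has zero NS and fully concordant identities", {
  syn <- synthesizePanel(panelSpec(seed = 10))
  params <- degradationParams(
    lambda = c(L1 = 0, L2 = 0, L3 = 0, L4O = 0, L4B = 0))
  study <- simulateStudy(studyDesign(), syn$panel, params, syn$diagnostics,
                         seed = 20)
  ns <- nsTable(study)
  expect_true(all(ns$nNS[!is.na(ns$nNS)] == 0L))
  ids <- identifyStudy(study, syn$panel)
  seqd <- ids[ids$fragment != "FAIL", ]
  expect_true(all(seqd$outcome == "CONCORDANT"))
})

test_that("mean NS percentage increases along processing levels", {
  syn <- synthesizePanel(panelSpec(seed = 30))
  means <- matrix(NA_real_, 40, 5,
                  dimnames = list(NULL, c("L1", "L2", "L3", "L4O", "L4B")))
  for (i in seq_len(nrow(means))) {
    study <- simulateStudy(studyDesign(), syn$panel, degradationParams(),
                           syn$diagnostics, seed = 100 + i)
    g <- groupMeanNS(nsTable(study), by = "level")
    means[i, g$level] <- g$mean_ns_percent
  }
  avg <- colMeans(means, na.rm = TRUE)
  expect_equal(unname(avg[["L1"]]), 0)
  expect_true(avg[["L1"]] < avg[["L2"]])
  expect_true(avg[["L2"]] < avg[["L3"]])
  expect_true(avg[["L3"]] < avg[["L4B"]])
  expect_true(avg[["L4O"]] < avg[["L4B"]])
})

test_that("studies round-trip through FASTA + manifest files", {
  syn <- synthesizePanel(panelSpec(seed = 12))
  study <- simulateStudy(studyDesign(), syn$panel, degradationParams(),
                         syn$diagnostics, seed = 3)
  dir <- withr::local_tempdir()
  writeStudy(study, dir)
  back <- readStudy(dir)
  expect_equal(nrow(back), nrow(study))
  key <- paste(study$individual, study$level)
  bkey <- paste(back$individual, back$level)
  expect_identical(back$sequence[match(key, bkey)], study$sequence)
  expect_identical(back$fragment[match(key, bkey)], study$fragment)
})
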