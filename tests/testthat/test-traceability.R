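makeRecord <- function(individual, level, fragment, sequence)
  list(individual = individual, level = level, fragment = fragment,
       sequence = sequence)

test_that("substitution counting is fragment-aware and ambiguity-safe", {
  set.seed(61)
  l1seq <- randomSeq(236)
  l1 <- makeRecord("i1", "L1", "AB", l1seq)

  same <- makeRecord("i1", "L4B", "B", substr(l1seq, 128, 236))
  expect_equal(countSubstitutions(same, l1)$nNS, 0L)

  diagB <- c(130L, 150L, 170L, 190L, 200L, 220L, 236L)
  mut <- mutateAt(l1seq, diagB)
  seven <- makeRecord("i1", "L4B", "B", substr(mut, 128, 236))
  cs <- countSubstitutions(seven, l1)
  expect_equal(cs$nNS, 7L)
  expect_identical(cs$columns, diagB)

  # an N at a substituted column removes it from the count
  v <- strsplit(substr(mut, 128, 236), "")[[1]]
  v[130 - 127] <- "N"
  withN <- makeRecord("i1", "L4B", "B", paste(v, collapse = ""))
  expect_equal(countSubstitutions(withN, l1)$nNS, 6L)

  expect_error(countSubstitutions(makeRecord("i2", "L2", "B",
                                             substr(l1seq, 128, 236)), l1),
               "pairing error")
  bOnly <- makeRecord("i1", "L1", "B", substr(l1seq, 128, 236))
  abQuery <- makeRecord("i1", "L2", "AB", l1seq)
  expect_error(countSubstitutions(abQuery, bOnly,
                                  fragments = defaultFragments(236)),
               "coordinate error")
})

test_that("NS percentages reproduce the printed worked values", {
  expect_equal(nsPercent(7, 109), 6.42)
  expect_equal(nsPercent(0, 236), 0)
  expect_equal(nsPercent(1, 117), 0.85)
  expect_error(nsPercent(1, 0), "positive")
  expect_error(nsPercent(-1, 109), "nNS")
  expect_error(nsPercent(110, 109), "nNS")
})

test_that("group means average unrounded per-specimen percentages", {
  rec <- data.frame(level = "L4O", area = "WCPO",
                    nNS = c(1L, 0L, 0L), fragment_length = 109L)
  expect_equal(groupMeanNS(rec, by = "level")$mean_ns_percent, 0.31)
  rec$nNS <- c(7L, 7L, 7L)
  expect_equal(groupMeanNS(rec, by = "level")$mean_ns_percent, 6.42)
  one <- data.frame(level = "L2", nNS = 2L, fragment_length = 236L)
  expect_equal(groupMeanNS(one, by = "level")$mean_ns_percent,
               nsPercent(2, 236))
  expect_error(groupMeanNS(rec[0, ]), "grouping error")
})

test_that("percent identity matches the inversion oracle and complements p-distance", {
  # brute-force inversion: which mismatch count k prints a given similarity?
  r2 <- function(x) floor(x * 100 + 0.5) / 100
  kFor <- function(pct, len)
    which(r2(100 * (len - 0:len) / len) == pct) - 1L
  set.seed(71)
  for (case in list(list(98.17, 109L), list(96.33, 109L),
                    list(98.73, 236L), list(96.19, 236L))) {
    pct <- case[[1]]; len <- case[[2]]
    k <- kFor(pct, len)
    expect_length(k, 1L)
    ref <- randomSeq(len)
    qry <- mutateAt(ref, sample(len, k))
    expect_equal(percentIdentity(qry, ref), pct)
  }
  # complementarity with p-distance on fully comparable columns
  for (i in 1:20) {
    a <- randomSeq(80); b <- randomSeq(80)
    expect_equal(percentIdentity(a, b), 100 - 100 * pDistance(a, b),
                 tolerance = 0.0051)
  }
})

test_that("every panel record self-identifies with 100.00 identity", {
  syn <- synthesizePanel(panelSpec(seed = 14))
  for (i in seq_len(length(syn$panel))) {
    s <- as.character(panelSequences(syn$panel))[i]
    for (fr in c("AB", "A", "B")) {
      q <- extractFragment(s, fragments(syn$panel)[fr])
      r <- identifySpecies(q, syn$panel, fragment = fr)
      expect_equal(r$best_identity, 100)
      expect_equal(r$status, "ASSIGNED")
      expect_identical(r$species_set, panelSpecies(syn$panel)[i])
    }
  }
})

test_that("ties, ambiguity and failures are classified per the similarity rule", {
  set.seed(81)
  refA <- randomSeq(236)
  diffCols <- sort(sample(236, 6))
  refB <- mutateAt(refA, diffCols)
  panel <- ReferencePanel(c(a = refA, b = refB), c("spA", "spB"),
                          fragments = defaultFragments(236))
  # query taking refB's base at 3 of the 6 differing columns is 3 mismatches
  # from each reference: both species tie at 98.73
  qv <- strsplit(refA, "")[[1]]
  wv <- strsplit(refB, "")[[1]]
  qv[diffCols[1:3]] <- wv[diffCols[1:3]]
  q <- paste(qv, collapse = "")
  rTie <- identifySpecies(q, panel, fragment = "AB")
  expect_equal(rTie$status, "TIE")
  expect_setequal(rTie$species_set, c("spA", "spB"))
  expect_equal(rTie$best_identity, 98.73)

  # sub-threshold best identity -> AMBIGUOUS
  rAmb <- identifySpecies(mutateAt(refA, sample(setdiff(1:236, diffCols), 12)),
                          panel, fragment = "AB")
  expect_true(rAmb$best_identity < 98)
  expect_equal(rAmb$status, "AMBIGUOUS")

  fail <- identifySpecies(makeRecord("x", "L3", "FAIL", NA), panel)
  expect_equal(fail$status, "FAILED")

  expect_equal(classifyOutcome(rTie, "spC"), "MISIDENTIFIED")
  expect_equal(classifyOutcome(rTie, "spA"), "MISIDENTIFIED")
  expect_equal(classifyOutcome(rTie, "spA", tieMode = "lenient"), "CONCORDANT")
  asg <- identifySpecies(refA, panel, fragment = "AB")
  expect_equal(classifyOutcome(asg, "spA"), "CONCORDANT")
  expect_equal(classifyOutcome(asg, "spB"), "MISIDENTIFIED")
  expect_equal(classifyOutcome(rAmb, "spA"), "AMBIGUOUS")
  expect_equal(classifyOutcome(fail, "spA"), "FAILED")
})

test_that("concordance cells always sum to their totals", {
  set.seed(91)
  outcomes <- data.frame(
    fragment = sample(c("AB", "A", "B"), 60, TRUE),
    level = sample(c("L1", "L2", "L3"), 60, TRUE),
    outcome = sample(c("CONCORDANT", "MISIDENTIFIED", "AMBIGUOUS", "FAILED"),
                     60, TRUE, prob = c(0.6, 0.2, 0.15, 0.05)))
  tab <- concordanceTable(outcomes)
  expect_true(all(tab$n_total == tab$n_concordant + tab$n_misidentified +
                    tab$n_ambiguous + tab$n_failed))
  expect_equal(sum(tab$n_total), 60L)
  empty <- concordanceTable(outcomes[0, ])
  expect_equal(nrow(empty), 0L)
})
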