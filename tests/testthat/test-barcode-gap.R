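test_that("p-distance handles ambiguity, symmetry and edge cases", {
  expect_equal(pDistance("ACGT", "ACGT"), 0)
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pDistance("ACNT", "ACGA"), 1 / 3)   # N column excluded
  expect_equal(pDistance("AC-T", "ACGA"), 1 / 3)   # gap column excluded
  expect_error(pDistance("ACG", "ACGT"), "coordinate error")
  expect_error(pDistance("NNNN", "ACGT"), "undefined")
  set.seed(21)
  for (i in 1:20) {
    a <- randomSeq(50); b <- randomSeq(50)
    expect_identical(pDistance(a, b), pDistance(b, a))
    expect_gte(pDistance(a, b), 0)
    expect_lte(pDistance(a, b), 1)
    expect_equal(pDistance(a, b), bruteDist(a, b))
  }
})

test_that("distance matrix matches brute force and ape on random panels", {
  skip_if_not_installed("ape")
  set.seed(31)
  for (rep in 1:3) {
    panel <- randomPanel(nrec = sample(3:20, 1), ncols = 60L)
    d <- distanceMatrix(panel)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    seqs <- as.character(panelSequences(panel))
    for (i in seq_len(nrow(d) - 1L)) for (j in (i + 1L):nrow(d))
      expect_equal(d[i, j], bruteDist(seqs[i], seqs[j]))
    # independent implementation: ape raw distance with pairwise deletion
    bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
    da <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
    expect_equal(unname(d), unname(da), tolerance = 1e-12)
  }
})

test_that("single-record panels give a zero matrix and empty pair table", {
  p1 <- ReferencePanel(c(a = randomSeq(20)), "x",
                       fragments = IRanges::IRanges(1, 20, names = "AB"))
  expect_identical(dim(distanceMatrix(p1)), c(1L, 1L))
  expect_equal(distanceMatrix(p1)[1, 1], 0)
  expect_equal(nrow(distanceTable(p1)), 0L)
})

test_that("barcode gap is detected on gapped panels and refused otherwise", {
  syn <- synthesizePanel(panelSpec(seed = 5))
  s <- barcodeGapSummary(syn$panel)
  expect_true(s$gap_detected)
  expect_gte(s$intra[1], 0); expect_lte(s$intra[2], 0.05)
  expect_gte(s$inter[1], 0.09); expect_lte(s$inter[2], 0.14)
  expect_true(s$inter[1] > s$intra[2])
  expect_true(s$threshold > s$intra[2] && s$threshold < s$inter[1])

  one <- ReferencePanel(c(a = randomSeq(30), b = randomSeq(30)),
                        c("x", "x"),
                        fragments = IRanges::IRanges(1, 30, names = "AB"))
  expect_error(barcodeGapSummary(one), "single species")

  # one label split across two true clusters at ~0.12: intra.max >= inter.min
  set.seed(41)
  base <- randomSeq(100)
  far <- mutateAt(base, sample(100, 12))
  other <- mutateAt(base, sample(100, 12))
  split <- ReferencePanel(
    c(a1 = base, a2 = far, b1 = other),
    species = c("spA", "spA", "spB"),
    fragments = IRanges::IRanges(1, 100, names = "AB"))
  expect_false(barcodeGapSummary(split)$gap_detected)
})

test_that("diagnostic positions satisfy fixation conditions", {
  panel <- tinyPanel()
  expect_identical(diagnosticPositions(panel, "sp1"), 5L)
  expect_identical(diagnosticPositions(panel, "sp2"), integer(0))
  expect_error(diagnosticPositions(panel, "nope"), "lookup error")

  # polymorphism inside the focal species disqualifies the column
  seqs <- as.character(panelSequences(panel))
  names(seqs) <- names(panelSequences(panel))
  seqs <- c(seqs, r1b = "ACGTACGTACGT")  # second sp1 record, no private base
  poly <- ReferencePanel(seqs, c("sp1", "sp2", "sp3", "sp4", "sp1"),
                         fragments = IRanges::IRanges(1, 12, names = "AB"))
  expect_identical(diagnosticPositions(poly, "sp1"), integer(0))
})

test_that("diagnostic positions equal the brute-force scan on random panels", {
  set.seed(51)
  for (rep in 1:4) {
    panel <- randomPanel(nrec = sample(6:20, 1), ncols = 50L, nsp = 3L,
                         pAmbig = 0.03)
    for (sp in unique(panelSpecies(panel)))
      expect_identical(diagnosticPositions(panel, sp),
                       bruteDiagnostics(panel, sp))
  }
})

test_that("fragment-restricted diagnostics nest inside the full scan", {
  syn <- synthesizePanel(panelSpec(seed = 8))
  frB <- fragments(syn$panel)["B"]
  bcols <- seq(IRanges::start(frB), IRanges::end(frB))
  for (sp in unique(panelSpecies(syn$panel))) {
    full <- diagnosticPositions(syn$panel, sp)
    inB <- diagnosticPositions(syn$panel, sp, fragment = "B")
    expect_identical(inB, intersect(full, bcols))
  }
})

test_that("mutating a focal record removes the diagnostic column", {
  syn <- synthesizePanel(panelSpec(seed = 13))
  sp <- unique(panelSpecies(syn$panel))[1]
  before <- diagnosticPositions(syn$panel, sp)
  col <- before[1]
  seqs <- as.character(panelSequences(syn$panel))
  names(seqs) <- names(panelSequences(syn$panel))
  i <- which(panelSpecies(syn$panel) == sp)[1]
  v <- strsplit(seqs[i], "")[[1]]
  # overwrite the focal record's distinguishing base with a contrasted base
  other <- which(panelSpecies(syn$panel) != sp)[1]
  v[col] <- strsplit(seqs[other], "")[[1]][col]
  seqs[i] <- paste(v, collapse = "")
  mutated <- ReferencePanel(seqs, panelSpecies(syn$panel),
                            fragments = fragments(syn$panel))
  expect_false(col %in% diagnosticPositions(mutated, sp))
  expect_setequal(setdiff(before, col),
                  intersect(before, diagnosticPositions(mutated, sp)))
})
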