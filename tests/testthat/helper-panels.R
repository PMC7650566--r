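# In-code fixtures and independent oracles shared by the tests.

# Tiny hand-checkable panel: 4 species x 1 sequence, 12 columns; column 5 is
# the single diagnostic for sp1, all other columns identical.
tinyPanel <- function() {
  base <- "ACGTACGTACGT"
  s1 <- base
  substr(s1, 5, 5) <- "T"   # sp1 private (others have A at column 5)
  seqs <- c(r1 = s1, r2 = base, r3 = base, r4 = base)
  ReferencePanel(seqs, species = c("sp1", "sp2", "sp3", "sp4"),
                 fragments = IRanges::IRanges(1, 12, names = "AB"))
}

# Random small panel for oracle comparisons: nrec records, ncol columns,
# nsp species, with N/gap characters sprinkled in.
randomPanel <- function(nrec = 10L, ncols = 40L, nsp = 3L, pAmbig = 0.05) {
  alpha <- c("A", "C", "G", "T")
  m <- matrix(sample(alpha, nrec * ncols, TRUE), nrec, ncols)
  amb <- matrix(runif(nrec * ncols) < pAmbig, nrec, ncols)
  m[amb] <- sample(c("N", "-"), sum(amb), TRUE)
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("r%02d", seq_len(nrec))
  ReferencePanel(seqs, species = paste0("sp", rep_len(seq_len(nsp), nrec)),
                 fragments = IRanges::IRanges(1, ncols, names = "AB"))
}

# Independent brute-force p-distance: explicit per-column loop.
bruteDist <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ncomp <- 0L; ndiff <- 0L
  for (k in seq_along(av)) {
    if (av[k] %in% c("A", "C", "G", "T") && bv[k] %in% c("A", "C", "G", "T")) {
      ncomp <- ncomp + 1L
      if (av[k] != bv[k]) ndiff <- ndiff + 1L
    }
  }
  ndiff / ncomp
}

# Independent brute-force diagnostic-position scan for a focal species
# against all others: per-column tabulation of within-species base sets.
bruteDiagnostics <- function(panel, focal, cols = NULL) {
  m <- toupper(as.matrix(panelSequences(panel)))
  sp <- panelSpecies(panel)
  if (is.null(cols)) cols <- seq_len(ncol(m))
  found <- integer()
  for (j in cols) {
    sets <- tapply(m[, j], sp, function(x) sort(unique(x)))
    if (any(vapply(sets, length, 1L) != 1L)) next
    bases <- vapply(sets, `[`, "", 1L)
    if (any(!bases %in% c("A", "C", "G", "T"))) next
    others <- bases[names(bases) != focal]
    if (all(others != bases[[focal]])) found <- c(found, j)
  }
  found
}

# Random ACGT-only sequence string.
randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Mutate a sequence string at given 1-based positions to a different base.
mutateAt <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}
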