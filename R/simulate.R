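## Synthetic-data generator: reference panels with a planted barcode gap,
## the canning study design, and level-wise sequence degradation.

.DEFAULT_SPECIES <- c(
  YFT = "Thunnus albacares",
  BET = "Thunnus obesus",
  SKJ = "Katsuwonus pelamis",
  LOT = "Thunnus tonggol")

#' Specification of a synthetic reference panel
#'
#' Defines the distance structure the generator must realize: intra-specific
#' pairwise p-distances inside `intraRange`, inter-specific distances inside
#' `interRange` (the two ranges must not touch, so a barcode gap exists by
#' construction), and at least `nDiagnosticInB` diagnostic columns per
#' species inside the B mini-barcode.
#'
#' @param nSpecies Number of species (default 4).
#' @param seqsPerSpecies Reference sequences per species (default 3).
#' @param intraRange,interRange Target p-distance ranges (defaults
#'   `c(0, 0.05)` and `c(0.09, 0.14)`).
#' @param nDiagnosticInB Minimum diagnostic columns per species inside
#'   fragment B (default 7).
#' @param alignmentLength Alignment columns (default 236).
#' @param species Optional species names (defaults to the four tropical
#'   tunas).
#' @param seed RNG seed used by [synthesizePanel()].
#' @return A list of class `SyntheticPanelSpec`.
#' @export
panelSpec <- function(nSpecies = 4L, seqsPerSpecies = 3L,
                      intraRange = c(0, 0.05), interRange = c(0.09, 0.14),
                      nDiagnosticInB = 7L, alignmentLength = 236L,
                      species = NULL, seed = NULL) {
  if (max(intraRange) >= min(interRange))
    stop("intra range must lie strictly below the inter range", call. = FALSE)
  if (is.null(species))
    species <- if (nSpecies == 4L) unname(.DEFAULT_SPECIES)
               else paste0("species_", seq_len(nSpecies))
  structure(list(nSpecies = as.integer(nSpecies),
                 seqsPerSpecies = as.integer(seqsPerSpecies),
                 intraRange = intraRange, interRange = interRange,
                 nDiagnosticInB = as.integer(nDiagnosticInB),
                 alignmentLength = as.integer(alignmentLength),
                 species = species, seed = seed),
            class = "SyntheticPanelSpec")
}

#' Synthesize a reference panel with a planted barcode gap
#'
#' Builds a background sequence and gives each species a disjoint set of
#' private columns (each carrying a base differing from the background), at
#' least `nDiagnosticInB` of them inside fragment B.  Private columns are by
#' construction diagnostic: fixed within every species and different in the
#' focal species from all others.  Per-record intra-specific noise is added
#' at non-private columns only, so diagnostics stay fixed.  The number of
#' private columns per species and the noise budget are sized from the
#' requested ranges; realized pairwise distances are verified post hoc and
#' the panel is regenerated (bounded retries) if any pair falls outside its
#' range.
#'
#' @param spec A [panelSpec()].
#' @param maxTries Bound on regeneration attempts before a feasibility error.
#' @return List with `panel` (a [ReferencePanel]) and `diagnostics` (named
#'   list, species -> planted diagnostic columns in increasing order).
#' @export
synthesizePanel <- function(spec = panelSpec(), maxTries = 25L) {
  L <- spec$alignmentLength
  nsp <- spec$nSpecies
  ## private columns per species: all inter-specific consensus distances are
  ## 2m/L; aim at the middle of the requested range
  m <- max(spec$nDiagnosticInB,
           round(L * mean(spec$interRange) / 2))
  if (2 * m / L > spec$interRange[2L] || nsp * m > L)
    stop("feasibility error: inter range unreachable at alignment length ",
         L, call. = FALSE)
  ## per-record noise budget: keep intra <= intra max and inter <= inter max
  E <- floor(min(spec$intraRange[2L] * L / 2,
                 (spec$interRange[2L] * L - 2 * m) / 2))
  E <- max(0L, E)
  frags <- defaultFragments(L)
  bCols <- if ("B" %in% names(frags))
    seq.int(IRanges::start(frags)["B" == names(frags)],
            IRanges::end(frags)["B" == names(frags)])
  else seq_len(L)
  if (length(bCols) < nsp * spec$nDiagnosticInB)
    stop("feasibility error: fragment B too short for the requested ",
         "diagnostic columns", call. = FALSE)

  build <- function() {
    background <- sample(DNA_BASES, L, replace = TRUE)
    inB <- resample(bCols, nsp * spec$nDiagnosticInB)
    outPool <- setdiff(seq_len(L), bCols)
    nOut <- m - spec$nDiagnosticInB
    outB <- if (nOut > 0L) resample(outPool, nsp * nOut) else integer()
    diag <- lapply(seq_len(nsp), function(i) {
      sort(c(inB[seq.int((i - 1L) * spec$nDiagnosticInB + 1L,
                         i * spec$nDiagnosticInB)],
             if (nOut > 0L) outB[seq.int((i - 1L) * nOut + 1L, i * nOut)]))
    })
    names(diag) <- spec$species
    allPrivate <- unlist(diag)
    consensus <- lapply(seq_len(nsp), function(i) {
      s <- background
      s[diag[[i]]] <- vapply(background[diag[[i]]], function(bb)
        sample(setdiff(DNA_BASES, bb), 1L), character(1L))
      s
    })
    freeCols <- setdiff(seq_len(L), allPrivate)
    seqs <- character(); species <- character(); ids <- character()
    for (i in seq_len(nsp)) {
      for (k in seq_len(spec$seqsPerSpecies)) {
        s <- consensus[[i]]
        e <- if (E > 0L) sample(0:E, 1L) else 0L
        if (e > 0L) {
          cols <- resample(freeCols, e)
          s[cols] <- vapply(s[cols], function(bb)
            sample(setdiff(DNA_BASES, bb), 1L), character(1L))
        }
        seqs <- c(seqs, paste(s, collapse = ""))
        species <- c(species, spec$species[i])
        ids <- c(ids, sprintf("%s_ref_%d", gsub("\\s+", "_", spec$species[i]), k))
      }
    }
    names(seqs) <- ids
    list(panel = ReferencePanel(seqs, species, fragments = frags),
         diagnostics = diag)
  }

  ok <- function(res) {
    tab <- distanceTable(res$panel)
    if (nrow(tab) == 0L) return(TRUE)
    intra <- tab$dist[tab$class == "intra"]
    inter <- tab$dist[tab$class == "inter"]
    all(intra >= spec$intraRange[1L] - 1e-12,
        intra <= spec$intraRange[2L] + 1e-12,
        inter >= spec$interRange[1L] - 1e-12,
        inter <= spec$interRange[2L] + 1e-12)
  }

  withSeed(spec$seed, {
    for (try in seq_len(maxTries)) {
      res <- build()
      if (ok(res)) return(res)
    }
    stop("feasibility error: could not realize the requested distance ",
         "structure in ", maxTries, " attempts", call. = FALSE)
  })
}

#' The canning-chain study design
#'
#' Species x FAO-area sampling cells with a fixed number of individuals per
#' cell, tracked through an ordered list of processing levels (L1 frozen, L2
#' defrosted, L3 cooked, L4O canned in oil, L4B canned in brine).  The
#' default reproduces the study layout: yellowfin and skipjack from 4 ocean
#' areas, bigeye from 2, longtail from 1, three individuals per cell -- 33
#' individuals, 165 level-records.
#'
#' @param cells `data.frame` with columns `code` (species short code),
#'   `species` (panel species label) and `area`; one row per sampling cell.
#' @param individualsPerCell Individuals sampled in every cell (default 3).
#' @param levels Ordered processing levels, starting with the baseline L1.
#' @return A list of class `StudyDesign`.
#' @export
studyDesign <- function(cells = NULL, individualsPerCell = 3L,
                        levels = c("L1", "L2", "L3", "L4O", "L4B")) {
  if (length(levels) == 0L || levels[1L] != "L1")
    stop("levels must be non-empty and start with L1", call. = FALSE)
  if (individualsPerCell < 1L)
    stop("at least one individual per cell", call. = FALSE)
  if (is.null(cells)) {
    areas <- list(YFT = c("AO", "IO", "EPO", "WCPO"),
                  SKJ = c("AO", "IO", "EPO", "WCPO"),
                  BET = c("IO", "EPO"),
                  LOT = "IO")
    cells <- do.call(rbind, lapply(names(areas), function(code)
      data.frame(code = code, species = unname(.DEFAULT_SPECIES[code]),
                 area = areas[[code]], stringsAsFactors = FALSE)))
  }
  structure(list(cells = cells,
                 individualsPerCell = as.integer(individualsPerCell),
                 levels = levels),
            class = "StudyDesign")
}

#' Expand a study design into specimen slots
#'
#' @param design A [studyDesign()].
#' @return `data.frame` with one row per individual per level: `individual`
#'   (e.g. `"YFT-AO-2"`), `code`, `species`, `area`, `level`.
#' @export
buildDesign <- function(design = studyDesign()) {
  cells <- design$cells
  ind <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(individual = sprintf("%s-%s-%d", cells$code[i], cells$area[i],
                                    seq_len(design$individualsPerCell)),
               code = cells$code[i], species = cells$species[i],
               area = cells$area[i], stringsAsFactors = FALSE)))
  out <- merge(ind, data.frame(level = design$levels), by = NULL)
  out$level <- factor(out$level, levels = design$levels)
  out <- out[order(match(out$individual, ind$individual), out$level), ]
  out$level <- as.character(out$level)
  rownames(out) <- NULL
  out
}

#' Level-dependent degradation parameters
#'
#' `lambda` gives the expected number of new substitutions introduced at each
#' level (Poisson, applied within the fragment available at that level); the
#' baseline L1 must be 0.  `diagnosticBias` is the fraction of substitution
#' mass directed at diagnostic columns (any species' planted diagnostics that
#' fall inside the fragment).  `amplification` is a per-level categorical
#' distribution over the amplifiable fragments (and `FAIL`); the default
#' reproduces the observed pattern: AB through L1-L2, AB or A at L3 with rare
#' failures, B (rarely A) after oil canning, B (rarely failure) after brine
#' canning.
#'
#' @param lambda Named non-negative vector, one entry per level.
#' @param diagnosticBias Fraction in `[0, 1]` (default 0.7).
#' @param amplification Named list: level -> named probability vector over
#'   `c("AB", "A", "B", "FAIL")` subsets, each summing to 1.
#' @param seed Optional RNG seed used by [simulateStudy()].
#' @return A list of class `DegradationParams`.
#' @export
degradationParams <- function(
    lambda = c(L1 = 0, L2 = 0.3, L3 = 1.5, L4O = 2.5, L4B = 5),
    diagnosticBias = 0.7,
    amplification = list(
      L1  = c(AB = 1),
      L2  = c(AB = 1),
      L3  = c(AB = 24, A = 7, FAIL = 2) / 33,
      L4O = c(B = 32, A = 1) / 33,
      L4B = c(B = 32, FAIL = 1) / 33),
    seed = NULL) {
  if (!is.null(lambda["L1"]) && !is.na(lambda["L1"]) && lambda[["L1"]] != 0)
    stop("lambda must be 0 at the L1 baseline", call. = FALSE)
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  if (diagnosticBias < 0 || diagnosticBias > 1)
    stop("diagnosticBias must lie in [0, 1]", call. = FALSE)
  sums <- vapply(amplification, sum, numeric(1L))
  if (any(abs(sums - 1) > 1e-8))
    stop("amplification probabilities must sum to 1 per level", call. = FALSE)
  structure(list(lambda = lambda, diagnosticBias = diagnosticBias,
                 amplification = amplification, seed = seed),
            class = "DegradationParams")
}

#' Apply one level of degradation to a sequence
#'
#' Draws `Poisson(lambda)` substitutions (truncated at the number of
#' available columns), directs a `diagnosticBias` fraction of them at
#' diagnostic columns and the rest uniformly at the remaining columns, and
#' replaces each hit base by one of the three alternatives chosen uniformly.
#' Deterministic under a fixed RNG state.
#'
#' @param sequence Character vector of bases (or character scalar) -- the
#'   current state of the specimen over the columns in `columns`.
#' @param lambda Expected substitution count at this level.
#' @param diagnosticBias Fraction of substitution mass aimed at
#'   `diagnosticColumns`.
#' @param diagnosticColumns Diagnostic columns (1-based alignment columns).
#' @param columns Alignment columns the sequence covers (defaults to
#'   `seq_along(sequence)`).
#' @return List with `sequence` (character vector over `columns`) and
#'   `columns` -- the alignment columns substituted at this level.
#' @export
applyDegradation <- function(sequence, lambda, diagnosticBias = 0,
                             diagnosticColumns = integer(),
                             columns = NULL) {
  s <- .asChars(sequence)
  if (is.null(columns)) columns <- seq_along(s)
  stopifnot(length(columns) == length(s))
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  n <- min(stats::rpois(1L, lambda), length(columns))
  if (n == 0L) return(list(sequence = s, columns = integer()))
  diagAvail <- intersect(diagnosticColumns, columns)
  otherAvail <- setdiff(columns, diagAvail)
  ## split the substitution mass between diagnostic and other columns; mass
  ## exceeding a pool's size is dropped, never redirected to the other pool
  nDiagTarget <- stats::rbinom(1L, n, diagnosticBias)
  nDiag <- min(nDiagTarget, length(diagAvail))
  nOther <- min(n - nDiagTarget, length(otherAvail))
  hit <- c(if (nDiag > 0L) resample(diagAvail, nDiag),
           if (nOther > 0L) resample(otherAvail, nOther))
  idx <- match(hit, columns)
  s[idx] <- vapply(s[idx], function(bb)
    sample(setdiff(DNA_BASES, bb), 1L), character(1L))
  list(sequence = s, columns = sort(hit))
}

#' Simulate the full canning-chain study
#'
#' Gives each designed individual an L1 haplotype (a panel sequence of its
#' species plus a little intra-specific noise at non-diagnostic columns),
#' then walks it through the processing levels.  Degradation is cumulative:
#' each level's sequence carries all substitutions of the previous levels
#' plus its own, drawn by [applyDegradation()] within the columns of the
#' fragment amplified at that level.  The amplified fragment (or FAIL) is
#' drawn per record from the level's amplification table.
#'
#' @param design A [studyDesign()].
#' @param panel A [ReferencePanel] covering the design's species.
#' @param params A [degradationParams()].
#' @param diagnostics Named list of planted diagnostic columns per species
#'   (from [synthesizePanel()]); computed with [diagnosticPositions()] when
#'   missing.
#' @param seed RNG seed (overrides `params$seed`).
#' @param l1NoiseMax Maximum intra-specific mutations given to an
#'   individual's L1 haplotype (default 2; kept small so the baseline stays
#'   unambiguously identifiable).
#' @param cumulative Logical; `FALSE` makes each level degrade the L1 state
#'   independently instead of the previous level's state.
#' @return `data.frame` of processed-sequence records: `individual,
#'   species_truth, species_label, area, level, fragment, sequence,
#'   truth_subs` (comma-separated substituted alignment columns; `sequence`
#'   is `NA` for amplification failures).
#' @export
simulateStudy <- function(design = studyDesign(), panel, params = degradationParams(),
                          diagnostics = NULL, seed = NULL,
                          l1NoiseMax = 2L, cumulative = TRUE) {
  if (is.null(seed)) seed <- params$seed
  if (is.null(diagnostics)) {
    sp <- unique(panelSpecies(panel))
    diagnostics <- lapply(sp, function(s) diagnosticPositions(panel, s))
    names(diagnostics) <- sp
  }
  allDiag <- sort(unique(unlist(diagnostics)))
  frags <- fragments(panel)
  fragCols <- lapply(seq_along(frags), function(i)
    seq.int(IRanges::start(frags)[i], IRanges::end(frags)[i]))
  names(fragCols) <- names(frags)
  L <- alignmentLength(panel)
  slots <- buildDesign(design)
  pm <- .panelMatrix(panel)
  freeCols <- setdiff(seq_len(L), allDiag)

  withSeed(seed, {
    inds <- unique(slots$individual)
    rows <- vector("list", nrow(slots))
    state <- list()        # individual -> full-length char vector
    l1state <- list()
    cumSubs <- list()      # individual -> integer columns
    for (ind in inds) {
      spName <- slots$species[slots$individual == ind][1L]
      refRows <- which(panelSpecies(panel) == spName)
      if (!length(refRows))
        stop("panel has no records for species '", spName, "'", call. = FALSE)
      hap <- pm[resample(refRows, 1L), ]
      e <- sample(0:max(0L, l1NoiseMax), 1L)
      if (e > 0L) {
        cols <- resample(freeCols, e)
        hap[cols] <- vapply(hap[cols], function(bb)
          sample(setdiff(DNA_BASES, bb), 1L), character(1L))
      }
      l1state[[ind]] <- state[[ind]] <- hap
      cumSubs[[ind]] <- integer()
    }
    for (i in seq_len(nrow(slots))) {
      ind <- slots$individual[i]; level <- slots$level[i]
      amp <- params$amplification[[level]]
      if (is.null(amp)) amp <- c(AB = 1)
      fragName <- sample(names(amp), 1L, prob = amp)
      lam <- if (level %in% names(params$lambda)) params$lambda[[level]] else 0
      targetCols <- if (fragName == "FAIL") fragCols[["AB"]] else fragCols[[fragName]]
      base <- if (cumulative) state[[ind]] else l1state[[ind]]
      if (lam > 0) {
        res <- applyDegradation(base[targetCols], lam,
                                params$diagnosticBias, allDiag, targetCols)
        base[targetCols] <- res$sequence
        newSubs <- res$columns
      } else newSubs <- integer()
      if (cumulative) {
        state[[ind]] <- base
        cumSubs[[ind]] <- sort(union(cumSubs[[ind]], newSubs))
        subsNow <- cumSubs[[ind]]
      } else subsNow <- newSubs
      if (fragName == "FAIL") {
        seqOut <- NA_character_; subsOut <- integer()
      } else {
        cols <- fragCols[[fragName]]
        seqOut <- paste(base[cols], collapse = "")
        subsOut <- intersect(subsNow, cols)
      }
      rows[[i]] <- data.frame(
        individual = ind, species_truth = slots$species[i],
        species_label = slots$species[i], area = slots$area[i],
        level = level, fragment = fragName, sequence = seqOut,
        truth_subs = paste(subsOut, collapse = ","),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a simulated study to per-level FASTA files and a manifest CSV
#'
#' @param study A [simulateStudy()] table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in unique(study$level)) {
    rows <- study[study$level == lv & !is.na(study$sequence), ]
    if (nrow(rows) == 0L) next
    seqs <- Biostrings::DNAStringSet(rows$sequence)
    names(seqs) <- sprintf("%s|%s|%s", rows$individual, lv, rows$fragment)
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(lv, ".fasta")),
                                width = 20001L)
  }
  manifest <- study[, c("individual", "species_label", "species_truth",
                        "area", "level", "fragment")]
  manifest$n_truth_subs <- vapply(study$truth_subs, function(x)
    if (!nzchar(x)) 0L else length(strsplit(x, ",")[[1L]]), integer(1L))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
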