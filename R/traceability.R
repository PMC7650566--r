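#' Count nucleotide substitutions relative to the specimen's frozen baseline
#'
#' The traceability statistic: for one specimen, the number of alignment
#' columns of the sequenced fragment at which the sequence obtained at a
#' later processing level differs from the frozen (L1) sequence of the same
#' individual.  Columns where either base is not an unambiguous A/C/G/T are
#' excluded.  The L1 record must cover the query's fragment (L1 is the
#' full-length AB fragment, which contains both mini-barcodes).
#'
#' @param query,l1 Records for the same individual: lists or one-row data
#'   frames with at least `individual`, `fragment` and `sequence` fields
#'   (the shape produced by [simulateStudy()]).
#' @param fragments Named [IRanges::IRanges] mapping fragment names to
#'   alignment columns; defaults to [defaultFragments()] at the L1 width.
#' @return List with `nNS` (integer count) and `columns` (1-based alignment
#'   columns of the substituted positions).
#' @export
countSubstitutions <- function(query, l1, fragments = NULL) {
  query <- as.list(query); l1 <- as.list(l1)
  if (!identical(as.character(query$individual), as.character(l1$individual)))
    stop("pairing error: query and L1 records belong to different individuals",
         call. = FALSE)
  l1seq <- .asChars(l1$sequence)
  if (is.null(fragments)) fragments <- defaultFragments(length(l1seq))
  frName <- function(x) as.character(x$fragment)
  colsOf <- function(name) {
    i <- match(name, names(fragments))
    if (is.na(i)) stop("unknown fragment '", name, "'", call. = FALSE)
    seq.int(IRanges::start(fragments)[i], IRanges::end(fragments)[i])
  }
  qcols <- colsOf(frName(query)); lcols <- colsOf(frName(l1))
  if (!all(qcols %in% lcols))
    stop("coordinate error: fragment ", frName(query),
         " not contained in the L1 fragment ", frName(l1), call. = FALSE)
  qv <- .asChars(query$sequence)
  if (length(qv) != length(qcols))
    stop("coordinate error: query sequence length ", length(qv),
         " does not match fragment length ", length(qcols), call. = FALSE)
  lv <- l1seq[match(qcols, lcols)]
  comp <- qv %in% DNA_BASES & lv %in% DNA_BASES
  diff <- comp & qv != lv
  list(nNS = sum(diff), columns = qcols[diff])
}

#' NS percentage of a substitution count
#'
#' `100 * nNS / fragmentLength`, reported to 2 decimals with halves rounded
#' away from zero.
#'
#' @param nNS Non-negative substitution count (<= `fragmentLength`).
#' @param fragmentLength Length of the sequenced fragment in bp.
#' @return Percentage to 2 decimals.
#' @export
nsPercent <- function(nNS, fragmentLength) {
  if (any(fragmentLength == 0)) stop("fragment length must be positive",
                                     call. = FALSE)
  if (any(nNS < 0) || any(nNS > fragmentLength))
    stop("nNS must lie in [0, fragment length]", call. = FALSE)
  roundHalfUp(100 * nNS / fragmentLength, 2L)
}

#' Per-record NS table for a processed study
#'
#' Computes, for every sequenced record of a study, the substitution count
#' and NS percentage relative to that individual's L1 record.  Records whose
#' amplification failed get `NA` counts.
#'
#' @param study A study table as produced by [simulateStudy()] (columns
#'   `individual, species_label, species_truth, area, level, fragment,
#'   sequence`).
#' @param fragments Optional fragment coordinates; defaults to
#'   [defaultFragments()] at the L1 sequence width.
#' @return `data.frame` with the identifying columns plus `nNS`,
#'   `fragment_length` and `ns_percent` (2 decimals).
#' @export
nsTable <- function(study, fragments = NULL) {
  out <- study[, intersect(c("individual", "species_label", "species_truth",
                             "area", "level", "fragment"), names(study))]
  out$nNS <- NA_integer_
  out$fragment_length <- NA_integer_
  out$ns_percent <- NA_real_
  for (ind in unique(study$individual)) {
    rows <- which(study$individual == ind)
    l1row <- rows[study$level[rows] == "L1"]
    if (length(l1row) != 1L || is.na(study$sequence[l1row])) next
    l1 <- as.list(study[l1row, ])
    for (r in rows) {
      if (is.na(study$sequence[r]) || study$fragment[r] %in% c("FAIL", "na"))
        next
      cs <- countSubstitutions(as.list(study[r, ]), l1, fragments)
      out$nNS[r] <- cs$nNS
      out$fragment_length[r] <- nchar(study$sequence[r])
      out$ns_percent[r] <- nsPercent(cs$nNS, out$fragment_length[r])
    }
  }
  out
}

#' Group-mean NS percentage
#'
#' Unweighted arithmetic mean of per-specimen NS percentages within each
#' group (the average reported per level and ocean).  The mean is taken over
#' the unrounded per-specimen percentages and displayed to 2 decimals.
#'
#' @param records NS records: a `data.frame` with `nNS` and `fragment_length`
#'   (preferred; the unrounded percentages are recomputed) or a precomputed
#'   `ns_percent` column, plus the grouping columns.
#' @param by Character vector of grouping column names present in `records`
#'   (default `level`, then `area` and species columns when present).
#' @return `data.frame` of group keys, `n` and `mean_ns_percent` (2 decimals).
#' @export
groupMeanNS <- function(records, by = NULL) {
  records <- records[!is.na(records$nNS %||% records$ns_percent), , drop = FALSE]
  if (nrow(records) == 0L) stop("grouping error: no records", call. = FALSE)
  pct <- if (!is.null(records$nNS) && !is.null(records$fragment_length))
    100 * records$nNS / records$fragment_length else records$ns_percent
  if (is.null(by))
    by <- intersect(c("level", "area", "species", "species_label"),
                    names(records))
  if (!length(by)) {
    return(data.frame(n = length(pct),
                      mean_ns_percent = roundHalfUp(mean(pct), 2L)))
  }
  keys <- records[, by, drop = FALSE]
  agg <- stats::aggregate(pct, by = as.list(keys), FUN = mean)
  cnt <- stats::aggregate(pct, by = as.list(keys), FUN = length)
  agg$n <- cnt$x
  agg$mean_ns_percent <- roundHalfUp(agg$x, 2L)
  agg$x <- NULL
  agg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent identity between two aligned fragments
#'
#' `100 * matches / comparable columns`, comparable as in [pDistance()]
#' (both bases in A/C/G/T), reported to 2 decimals with halves rounded away
#' from zero.  On fully comparable columns this is the exact complement of
#' the p-distance: `percentIdentity + 100 * pDistance = 100`.
#'
#' @param query,reference Aligned sequences of equal length.
#' @return Percentage to 2 decimals.
#' @export
percentIdentity <- function(query, reference) {
  roundHalfUp(100 * (1 - pDistance(query, reference)), 2L)
}

#' Identify the species of a degraded fragment against the reference panel
#'
#' Computes the percent identity of the query fragment against the matching
#' fragment slice of every panel record and applies the similarity rule: the
#' query is ASSIGNED to the species attaining the best identity when that
#' identity meets the threshold and a single species attains it; TIE when
#' several species tie at the best identity (ties resolved at the reported
#' 2-decimal precision); AMBIGUOUS when the best identity falls below the
#' threshold; FAILED when there is no sequence (amplification failure).
#'
#' @param query Either a study record (list with `sequence` and `fragment`)
#'   or a character sequence (then give `fragment`).
#' @param panel A [ReferencePanel].
#' @param threshold Identity threshold in percent (default 98).
#' @param fragment Fragment name when `query` is a bare sequence.
#' @return List of class `IdentificationResult`: `query` id (when known),
#'   `best_identity`, `species_set`, `status`.
#' @export
identifySpecies <- function(query, panel, threshold = 98, fragment = NULL) {
  if (length(panel) == 0L) stop("panel error: empty panel", call. = FALSE)
  qid <- NA_character_
  if (is.list(query) || is.data.frame(query)) {
    q <- as.list(query)
    qid <- as.character(q$individual %||% NA_character_)
    fragment <- as.character(q$fragment)
    query <- q$sequence
  }
  if (is.null(fragment)) stop("fragment name required", call. = FALSE)
  if (is.null(query) || length(query) == 0L || is.na(query) ||
      fragment %in% c("FAIL", "na")) {
    return(structure(list(query = qid, best_identity = NA_real_,
                          species_set = character(), status = "FAILED"),
                     class = "IdentificationResult"))
  }
  cols <- .fragmentColumns(panel, fragment)
  m <- .panelMatrix(panel)[, cols, drop = FALSE]
  qv <- .asChars(query)
  if (length(qv) != length(cols))
    stop("coordinate error: query length ", length(qv),
         " does not match fragment ", fragment, " length ", length(cols),
         call. = FALSE)
  ident <- apply(m, 1L, function(ref) {
    comp <- qv %in% DNA_BASES & ref %in% DNA_BASES
    if (!any(comp)) return(NA_real_)
    roundHalfUp(100 * mean(qv[comp] == ref[comp]), 2L)
  })
  best <- max(ident, na.rm = TRUE)
  set <- sort(unique(panelSpecies(panel)[!is.na(ident) & ident == best]))
  status <- if (best < threshold) "AMBIGUOUS"
            else if (length(set) > 1L) "TIE" else "ASSIGNED"
  structure(list(query = qid, best_identity = best, species_set = set,
                 status = status), class = "IdentificationResult")
}

#' @exportS3Method base::print
print.IdentificationResult <- function(x, ...) {
  cat("IdentificationResult:", x$status,
      if (length(x$species_set)) paste0("[", paste(x$species_set, collapse = ", "),
                                        "] at ", sprintf("%.2f%%", x$best_identity))
      else "", "\n")
  invisible(x)
}

#' Classify an identification against the morphological label
#'
#' CONCORDANT when the genetic assignment recovers the morphological species;
#' MISIDENTIFIED when an assignment at or above the threshold names a
#' different species; AMBIGUOUS and FAILED pass through.  Ties: under the
#' default `"strict"` mode any multi-species tie counts as MISIDENTIFIED
#' (ties are reported among the misidentified samples in this bookkeeping);
#' under `"lenient"` a tie whose set contains the morphological species
#' counts as CONCORDANT.
#'
#' @param result An `IdentificationResult` from [identifySpecies()].
#' @param morphological Morphological species label of the specimen.
#' @param tieMode `"strict"` (default) or `"lenient"`.
#' @return One of `"CONCORDANT"`, `"MISIDENTIFIED"`, `"AMBIGUOUS"`,
#'   `"FAILED"`.
#' @export
classifyOutcome <- function(result, morphological,
                            tieMode = c("strict", "lenient")) {
  tieMode <- match.arg(tieMode)
  switch(result$status,
    FAILED = "FAILED",
    AMBIGUOUS = "AMBIGUOUS",
    ASSIGNED = if (identical(result$species_set, as.character(morphological)))
      "CONCORDANT" else "MISIDENTIFIED",
    TIE = if (tieMode == "lenient" && morphological %in% result$species_set)
      "CONCORDANT" else "MISIDENTIFIED")
}

#' Identify every record of a processed study
#'
#' Runs [identifySpecies()] and [classifyOutcome()] over all records.
#'
#' @param study Study table ([simulateStudy()] shape).
#' @param panel A [ReferencePanel].
#' @param threshold Identity threshold in percent.
#' @param tieMode Tie handling, see [classifyOutcome()].
#' @return `data.frame` with `individual, species_label, area, level,
#'   fragment, best_identity, species_set` (semicolon-separated), `status`,
#'   `outcome`.
#' @export
identifyStudy <- function(study, panel, threshold = 98,
                          tieMode = c("strict", "lenient")) {
  tieMode <- match.arg(tieMode)
  res <- lapply(seq_len(nrow(study)), function(i) {
    r <- identifySpecies(as.list(study[i, ]), panel, threshold)
    data.frame(
      individual = study$individual[i],
      species_label = study$species_label[i],
      area = study$area[i], level = study$level[i],
      fragment = study$fragment[i],
      best_identity = r$best_identity,
      species_set = paste(r$species_set, collapse = ";"),
      status = r$status,
      outcome = classifyOutcome(r, study$species_label[i], tieMode),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Concordance table by fragment and level
#'
#' Tabulates identification outcomes into counts of concordant,
#' misidentified, ambiguous and failed records per group, with the percent
#' concordant to 2 decimals.  Counts always sum to `n_total` per cell.
#'
#' @param outcomes `data.frame` with an `outcome` column plus the grouping
#'   columns.
#' @param by Grouping columns (default fragment and level).
#' @return `data.frame` of group keys and columns `n_total, n_concordant,
#'   n_misidentified, n_ambiguous, n_failed, percent_concordant`.
#' @export
concordanceTable <- function(outcomes, by = c("fragment", "level")) {
  by <- intersect(by, names(outcomes))
  lvls <- c("CONCORDANT", "MISIDENTIFIED", "AMBIGUOUS", "FAILED")
  if (nrow(outcomes) == 0L) {
    empty <- outcomes[0L, by, drop = FALSE]
    for (col in c("n_total", "n_concordant", "n_misidentified",
                  "n_ambiguous", "n_failed"))
      empty[[col]] <- integer(0)
    empty$percent_concordant <- numeric(0)
    return(empty)
  }
  oc <- factor(outcomes$outcome, levels = lvls)
  keys <- if (length(by)) outcomes[, by, drop = FALSE]
          else data.frame(group = rep("all", nrow(outcomes)))
  tab <- stats::aggregate(seq_len(nrow(outcomes)), by = as.list(keys),
                          FUN = length)
  counts <- lapply(lvls, function(l)
    stats::aggregate(oc == l, by = as.list(keys), FUN = sum)$x)
  out <- tab
  names(out)[ncol(out)] <- "n_total"
  out$n_concordant <- counts[[1L]]
  out$n_misidentified <- counts[[2L]]
  out$n_ambiguous <- counts[[3L]]
  out$n_failed <- counts[[4L]]
  out$percent_concordant <- roundHalfUp(
    100 * out$n_concordant / out$n_total, 2L)
  out
}
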