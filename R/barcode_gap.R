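#' Pairwise p-distance between aligned sequences
#'
#' Proportion of comparable columns at which the two sequences differ.  A
#' column is comparable when both characters are unambiguous bases (A, C, G,
#' T); columns with N or a gap in either sequence are excluded from both the
#' numerator and the denominator (pairwise deletion).
#'
#' @param a,b Aligned sequences of equal length (character scalars or
#'   [Biostrings::DNAString]s).
#' @return A proportion in `[0, 1]`.
#' @export
pDistance <- function(a, b) {
  av <- .asChars(a); bv <- .asChars(b)
  if (length(av) != length(bv))
    stop("coordinate error: sequences have unequal lengths (",
         length(av), " vs ", length(bv), ")", call. = FALSE)
  comp <- av %in% DNA_BASES & bv %in% DNA_BASES
  if (!any(comp))
    stop("undefined distance: no comparable columns", call. = FALSE)
  sum(av[comp] != bv[comp]) / sum(comp)
}

#' Pairwise p-distance matrix over a panel
#'
#' @param panel A validated [ReferencePanel] (single-species panels are
#'   allowed here; only [barcodeGapSummary()] needs two).
#' @param fragment Fragment name (`"AB"`, `"A"`, `"B"`) restricting the
#'   computation to that fragment's columns, or `NULL` for the full alignment.
#' @return Symmetric numeric matrix (zero diagonal) with record ids as
#'   dimnames.
#' @export
distanceMatrix <- function(panel, fragment = NULL) {
  m <- .panelMatrix(panel)
  if (!is.null(fragment)) m <- m[, .fragmentColumns(panel, fragment), drop = FALSE]
  n <- nrow(m)
  ids <- names(panelSequences(panel))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  ok <- matrix(m %in% DNA_BASES, n, ncol(m))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("undefined distance between '", ids[i], "' and '", ids[j],
           "': no comparable columns", call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  d
}

#' Long-format pairwise distance table
#'
#' One row per unordered record pair, classified `intra` (same species label)
#' or `inter`.
#'
#' @inheritParams distanceMatrix
#' @return `data.frame` with columns `id_a, id_b, species_a, species_b, dist,
#'   class`.
#' @export
distanceTable <- function(panel, fragment = NULL) {
  d <- distanceMatrix(panel, fragment)
  sp <- panelSpecies(panel)
  n <- nrow(d)
  if (n < 2L)
    return(data.frame(id_a = character(), id_b = character(),
                      species_a = character(), species_b = character(),
                      dist = numeric(), class = character()))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(
    id_a = rownames(d)[idx[, 1L]], id_b = colnames(d)[idx[, 2L]],
    species_a = sp[idx[, 1L]], species_b = sp[idx[, 2L]],
    dist = d[idx],
    class = ifelse(sp[idx[, 1L]] == sp[idx[, 2L]], "intra", "inter"),
    stringsAsFactors = FALSE)
}

#' Barcode-gap summary of a reference panel
#'
#' Partitions all pairwise p-distances into intra-specific and inter-specific
#' sets using the panel's species labels and applies a single-pass gap
#' criterion: a barcode gap is reported when the smallest inter-specific
#' distance exceeds the largest intra-specific distance and the gap width
#' exceeds `(X - 1)` times the maximum intra-specific distance.  This is a
#' deliberate single-pass simplification of the recursive ABGD procedure for
#' the confirmatory case where species labels are known.
#'
#' @param panel A [ReferencePanel] with at least two species.
#' @param X Relative gap width (default 1.5, the ABGD default).
#' @param fragment Optional fragment restriction as in [distanceMatrix()].
#' @return A list of class `DistanceSummary`: `intra` and `inter` ranges
#'   (`c(min, max)`, `NA`s when no such pairs exist), `gap_detected`,
#'   `relative_gap_width`, and `threshold` (gap midpoint when detected).
#' @export
barcodeGapSummary <- function(panel, X = 1.5, fragment = NULL) {
  sp <- unique(panelSpecies(panel))
  if (length(sp) < 2L)
    stop("no inter-specific distances: panel has a single species",
         call. = FALSE)
  tab <- distanceTable(panel, fragment)
  intra <- tab$dist[tab$class == "intra"]
  inter <- tab$dist[tab$class == "inter"]
  intraRange <- if (length(intra)) range(intra) else c(NA_real_, NA_real_)
  interRange <- if (length(inter)) range(inter) else c(NA_real_, NA_real_)
  intraMax <- if (length(intra)) max(intra) else 0
  gap <- length(inter) > 0L &&
    interRange[1L] > intraMax &&
    (interRange[1L] - intraMax) > (X - 1) * intraMax
  structure(list(
    intra = intraRange, inter = interRange,
    gap_detected = gap, relative_gap_width = X,
    threshold = if (gap) (interRange[1L] + intraMax) / 2 else NA_real_),
    class = "DistanceSummary")
}

#' @exportS3Method base::print
print.DistanceSummary <- function(x, ...) {
  fmt <- function(r) if (anyNA(r)) "none" else
    sprintf("[%.4f, %.4f]", r[1L], r[2L])
  cat("Barcode gap summary (X =", x$relative_gap_width, ")\n")
  cat("  intra-specific p-distance:", fmt(x$intra), "\n")
  cat("  inter-specific p-distance:", fmt(x$inter), "\n")
  cat("  gap detected:", x$gap_detected,
      if (x$gap_detected) sprintf("(threshold %.4f)", x$threshold) else "",
      "\n")
  invisible(x)
}

#' Diagnostic nucleotide positions for a species
#'
#' A column is diagnostic for the focal species when (i) the focal species is
#' fixed for one base there, (ii) every contrasted species is fixed, and
#' (iii) the focal base differs from the fixed base of every contrasted
#' species.  Columns containing N or a gap in any involved record are
#' disqualified (conservative: ambiguity never supports a diagnosis).
#'
#' @param panel A [ReferencePanel].
#' @param focal Focal species label; or a length-2 character vector to run a
#'   pairwise contrast between exactly two species.
#' @param fragment Optional fragment name restricting the scan; `NULL` scans
#'   the full alignment.
#' @return Increasing integer vector of 1-based alignment columns.
#' @export
diagnosticPositions <- function(panel, focal, fragment = NULL) {
  sp <- panelSpecies(panel)
  if (!all(focal %in% sp))
    stop("lookup error: unknown species label(s): ",
         paste(setdiff(focal, sp), collapse = ", "), call. = FALSE)
  contrast <- if (length(focal) >= 2L) focal[-1L] else setdiff(unique(sp), focal)
  focal <- focal[1L]
  m <- .panelMatrix(panel)
  cols <- if (is.null(fragment)) seq_len(ncol(m)) else .fragmentColumns(panel, fragment)
  groups <- c(list(which(sp == focal)),
              lapply(contrast, function(s) which(sp == s)))
  fixedBase <- function(rows, j) {
    b <- unique(m[rows, j])
    if (length(b) == 1L && b %in% DNA_BASES) b else NA_character_
  }
  out <- integer()
  for (j in cols) {
    bases <- vapply(groups, fixedBase, character(1L), j = j)
    if (anyNA(bases)) next
    if (all(bases[-1L] != bases[1L])) out <- c(out, j)
  }
  out
}

#' Diagnostic-position table across all species of a panel
#'
#' @inheritParams diagnosticPositions
#' @return `data.frame` with columns `species, fragment, column, focal_base,
#'   contrast_bases` (contrast bases comma-separated in panel species order).
#' @export
diagnosticTable <- function(panel, fragment = NULL) {
  m <- .panelMatrix(panel)
  species <- unique(panelSpecies(panel))
  fragName <- if (is.null(fragment)) "full" else fragment
  rows <- lapply(species, function(s) {
    cols <- diagnosticPositions(panel, s, fragment)
    if (!length(cols)) return(NULL)
    foc <- vapply(cols, function(j) m[panelSpecies(panel) == s, j][1L],
                  character(1L))
    ctr <- vapply(cols, function(j) {
      others <- setdiff(species, s)
      paste(vapply(others, function(o)
        m[panelSpecies(panel) == o, j][1L], character(1L)), collapse = ",")
    }, character(1L))
    data.frame(species = s, fragment = fragName, column = cols,
               focal_base = foc, contrast_bases = ctr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), fragment = character(),
                      column = integer(), focal_base = character(),
                      contrast_bases = character())
  out
}
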