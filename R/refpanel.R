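#' Default fragment coordinate system
#'
#' The barcode region is a 236-column cytochrome b alignment (anchored to the
#' *Thunnus thynnus* mitogenome, positions 14665--14901).  Three fragments are
#' amplifiable: the full-length `AB` (236 bp) and the two mini-barcodes `A`
#' (117 bp, 5' end, columns 1--117) and `B` (109 bp, 3' end, columns
#' 128--236).  The exact primer layout of A and B inside AB is a convention
#' of this package (117 + 109 < 236 leaves a 10-column inter-primer region);
#' both coordinates can be overridden.
#'
#' @param alignmentLength Number of alignment columns (default 236).
#' @param a,b Optional `c(start, end)` overrides for the A and B fragments.
#' @return A named [IRanges::IRanges] with elements `AB`, `A`, `B` (only `AB`
#'   when `alignmentLength` cannot accommodate the defaults and no overrides
#'   are given).
#' @export
defaultFragments <- function(alignmentLength = 236L, a = NULL, b = NULL) {
  alignmentLength <- as.integer(alignmentLength)
  if (is.null(a) && alignmentLength >= 117L) a <- c(1L, 117L)
  if (is.null(b) && alignmentLength >= 236L)
    b <- c(alignmentLength - 108L, alignmentLength)
  starts <- 1L; ends <- alignmentLength; nms <- "AB"
  if (!is.null(a)) { starts <- c(starts, a[1L]); ends <- c(ends, a[2L]); nms <- c(nms, "A") }
  if (!is.null(b)) { starts <- c(starts, b[1L]); ends <- c(ends, b[2L]); nms <- c(nms, "B") }
  if (any(starts < 1L) || any(ends > alignmentLength) || any(starts > ends))
    stop("fragment coordinates out of bounds for alignment of length ",
         alignmentLength, call. = FALSE)
  IRanges::IRanges(start = starts, end = ends, names = nms)
}

.defaultAnchor <- function() {
  list(genome = "NC_004901", start = 14665L, end = 14901L)
}

#' Construct a ReferencePanel from sequences and labels
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector of
#'   equal-length aligned sequences.
#' @param species Character vector of species labels, one per sequence.
#' @param area Optional character vector of FAO-area/ocean labels.
#' @param fragments Named [IRanges::IRanges] of fragment coordinates; defaults
#'   to [defaultFragments()] at the alignment width.
#' @param anchor Mitogenome anchor, a list `(genome, start, end)`.
#' @return A validated [ReferencePanel].
#' @export
ReferencePanel <- function(sequences, species, area = NULL, fragments = NULL,
                           anchor = .defaultAnchor()) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  n <- length(sequences)
  if (is.null(area)) area <- rep(NA_character_, n)
  if (is.null(fragments)) {
    w <- if (n > 0L) Biostrings::width(sequences)[1L] else 0L
    fragments <- defaultFragments(w)
  }
  new("ReferencePanel", sequences = sequences,
      species = as.character(species), area = as.character(area),
      fragments = fragments, anchor = anchor)
}

#' Load a reference panel from FASTA + metadata CSV
#'
#' Reads a pre-aligned, fixed-length reference alignment (wrapped or
#' single-line FASTA) and a metadata table with columns `id`, `species` and
#' optionally `area`.  Every FASTA record must appear in the metadata with a
#' non-empty species label; sequences must all have the same length and use
#' only the characters A, C, G, T, N and `-`.
#'
#' @param alignmentPath Path to the FASTA alignment.
#' @param metadataPath Path to the metadata CSV.
#' @param fragments Optional fragment coordinate override (named
#'   [IRanges::IRanges]); defaults to [defaultFragments()].
#' @param anchor Optional mitogenome anchor list.
#' @return A validated [ReferencePanel] with fragment definitions attached.
#' @export
loadPanel <- function(alignmentPath, metadataPath, fragments = NULL,
                      anchor = .defaultAnchor()) {
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(alignmentPath),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("alphabet error: invalid sequence characters in ", alignmentPath,
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0L) stop("alignment error: empty FASTA", call. = FALSE)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(range(Biostrings::width(seqs)), collapse = "-"), ")",
         call. = FALSE)
  bad <- vapply(as.character(seqs), function(s)
    any(!strsplit(toupper(s), "")[[1L]] %in% PANEL_ALPHABET), logical(1L))
  if (any(bad))
    stop("alphabet error: illegal character in ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  meta <- utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  if (!all(c("id", "species") %in% names(meta)))
    stop("metadata error: CSV must have columns 'id' and 'species'",
         call. = FALSE)
  idx <- match(names(seqs), meta$id)
  if (anyNA(idx))
    stop("metadata error: FASTA id(s) absent from metadata: ",
         paste(names(seqs)[is.na(idx)], collapse = ", "), call. = FALSE)
  species <- meta$species[idx]
  if (any(is.na(species) | !nzchar(species)))
    stop("metadata error: empty species label for ",
         paste(names(seqs)[is.na(species) | !nzchar(species)],
               collapse = ", "), call. = FALSE)
  area <- if ("area" %in% names(meta)) meta$area[idx] else NULL
  panel <- ReferencePanel(seqs, species, area, fragments = fragments,
                          anchor = anchor)
  ## hard invariants only; a single-species panel loads (inter-specific
  ## statistics will refuse it later) but validatePanel still reports it
  viol <- grep("fewer than two species", validatePanel(panel),
               invert = TRUE, value = TRUE)
  if (length(viol)) stop("invalid panel: ", paste(viol, collapse = "; "),
                         call. = FALSE)
  panel
}

#' Write a reference panel to FASTA + metadata CSV
#'
#' Sequences are written single-line; metadata as `id,species,area`.
#' `loadPanel(writePanel(...))` round-trips the panel byte-identically in
#' sequence content and labels.
#'
#' @param panel A [ReferencePanel].
#' @param alignmentPath,metadataPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writePanel <- function(panel, alignmentPath, metadataPath) {
  Biostrings::writeXStringSet(panelSequences(panel), alignmentPath,
                              width = max(20001L, alignmentLength(panel)))
  utils::write.csv(
    data.frame(id = names(panelSequences(panel)),
               species = panelSpecies(panel),
               area = panelArea(panel), stringsAsFactors = FALSE),
    metadataPath, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(alignmentPath, metadataPath))
}

#' Validate a reference panel
#'
#' Checks the panel invariants and returns the violations as a character
#' vector (empty when the panel is valid) instead of throwing, so that a
#' partially built or filtered panel can be inspected.
#'
#' Checked: equal sequence lengths; non-empty species label per record;
#' unique record ids; alphabet restricted to A/C/G/T/N/-; at least two
#' species (inter-specific computations need >= 2); no species left with zero
#' records.
#'
#' @param panel A [ReferencePanel].
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validatePanel <- function(panel) {
  viol <- character()
  seqs <- panelSequences(panel)
  if (length(seqs) == 0L) return("panel has no sequences")
  if (length(unique(Biostrings::width(seqs))) != 1L)
    viol <- c(viol, "sequences have unequal lengths")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    viol <- c(viol, "every record needs a non-empty id")
  } else if (anyDuplicated(ids)) {
    viol <- c(viol, paste0("duplicate id: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sp <- panelSpecies(panel)
  if (any(is.na(sp) | !nzchar(sp)))
    viol <- c(viol, "empty species label")
  tab <- table(factor(sp[!is.na(sp) & nzchar(sp)]))
  if (any(tab == 0L))
    viol <- c(viol, paste0("species with zero records: ",
                           paste(names(tab)[tab == 0L], collapse = ", ")))
  if (length(tab) < 2L)
    viol <- c(viol, "fewer than two species: inter-specific statistics undefined")
  chars <- unique(unlist(strsplit(toupper(as.character(seqs)), "")))
  bad <- setdiff(chars, PANEL_ALPHABET)
  if (length(bad))
    viol <- c(viol, paste0("illegal character(s): ", paste(bad, collapse = " ")))
  viol
}

#' Extract a fragment from an aligned sequence
#'
#' Returns the alignment columns `start..end` (1-based, inclusive) of a
#' fragment definition.
#'
#' @param sequence An aligned sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param frag A fragment definition: one element of a panel's [fragments()]
#'   (an [IRanges::IRanges] of length 1) or a `c(start, end)` integer pair.
#' @return Character scalar of length `end - start + 1`.
#' @export
extractFragment <- function(sequence, frag) {
  if (is(frag, "IRanges")) {
    if (length(frag) != 1L) stop("frag must be a single range", call. = FALSE)
    s <- IRanges::start(frag); e <- IRanges::end(frag)
  } else {
    s <- as.integer(frag[1L]); e <- as.integer(frag[2L])
  }
  seqc <- if (is(sequence, "XString")) as.character(sequence) else as.character(sequence)
  if (s < 1L || e < s) stop("coordinate error: invalid fragment bounds", call. = FALSE)
  if (nchar(seqc) < e)
    stop("coordinate error: fragment end ", e, " exceeds sequence length ",
         nchar(seqc), call. = FALSE)
  substring(seqc, s, e)
}
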