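#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom IRanges IRanges start end width
NULL

#' ReferencePanel: a fixed-coordinate cytochrome b reference alignment
#'
#' Container for an aligned, fixed-length barcode reference panel: one
#' sequence per reference record, a species label (and optional FAO-area
#' label) per record, the mitogenome anchor of the alignment, and the
#' fragment coordinate system (full-length \code{AB} plus the \code{A} and
#' \code{B} mini-barcodes).  All downstream coordinates -- fragments,
#' diagnostic positions, substitution columns -- are 1-based columns of this
#' alignment.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of equal-width aligned
#'   sequences (alphabet restricted to A, C, G, T, N and the gap character).
#' @slot species Character vector, one species label per sequence.
#' @slot area Character vector of FAO-area / ocean labels (may be `NA`).
#' @slot fragments Named [IRanges::IRanges] giving 1-based inclusive start and
#'   end columns of each amplifiable fragment.
#' @slot anchor List with elements `genome`, `start`, `end`: the mitogenome
#'   region the alignment corresponds to (1-based coordinates).
#'
#' @seealso [loadPanel()], [validatePanel()], [extractFragment()],
#'   [synthesizePanel()]
#' @export
setClass("ReferencePanel",
  representation(
    sequences = "DNAStringSet",
    species   = "character",
    area      = "character",
    fragments = "IRanges",
    anchor    = "list"
  )
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@species) != n)
    msg <- c(msg, "species labels must match number of sequences")
  if (length(object@area) != n)
    msg <- c(msg, "area labels must match number of sequences")
  if (n > 0L && length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "all sequences must have the same alignment width")
  if (length(object@fragments) > 0L) {
    if (is.null(names(object@fragments)))
      msg <- c(msg, "fragments must be named")
    w <- alignmentLength(object)
    if (n > 0L && any(IRanges::end(object@fragments) > w |
                      IRanges::start(object@fragments) < 1L))
      msg <- c(msg, "fragment coordinates must lie within the alignment")
  }
  if (length(msg)) msg else TRUE
})

#' GLMMFit: a fitted Poisson mixed model of substitution counts
#'
#' Result of [fitPoissonGLMM()].  Carries the fixed-effect estimates, the
#' random-intercept variance components, the maximized log-likelihood and the
#' number of estimated parameters needed for likelihood-ratio testing, plus
#' the underlying fitted model object for residual-based diagnostics.
#'
#' @slot fixef Named numeric vector of fixed-effect estimates (log scale).
#' @slot vcomp Named numeric vector of random-intercept variances.
#' @slot logLik Maximized log-likelihood (Laplace approximation).
#' @slot npar Number of estimated parameters (fixed effects plus variance
#'   components).
#' @slot converged Logical convergence flag (`FALSE` for degenerate or
#'   singular fits and optimizer failures).
#' @slot model The underlying fitted model (a `glmerMod`, or a `glm` when the
#'   model has no random terms).
#' @slot records The model frame the fit was computed from.
#'
#' @seealso [likelihoodRatioTest()], [overdispersion()]
#' @export
setClass("GLMMFit",
  representation(
    fixef     = "numeric",
    vcomp     = "numeric",
    logLik    = "numeric",
    npar      = "integer",
    converged = "logical",
    model     = "ANY",
    records   = "data.frame"
  )
)

setValidity("GLMMFit", function(object) {
  msg <- character()
  if (any(object@vcomp < 0)) msg <- c(msg, "variance components must be >= 0")
  if (object@npar != length(object@fixef) + length(object@vcomp))
    msg <- c(msg, "npar must equal fixed effects + variance components")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferencePanel Number of reference records in the panel.
#' @param x,object A `ReferencePanel`.
#' @export
setMethod("length", "ReferencePanel", function(x) length(x@sequences))

#' Accessors for ReferencePanel slots
#'
#' @param panel A [ReferencePanel].
#' @return `panelSequences()` the [Biostrings::DNAStringSet];
#'   `panelSpecies()`/`panelArea()` character vectors; `fragments()` the named
#'   [IRanges::IRanges] of fragment coordinates; `alignmentLength()` the
#'   number of alignment columns; `panelAnchor()` the mitogenome anchor list.
#' @export
panelSequences <- function(panel) panel@sequences

#' @rdname panelSequences
#' @export
panelSpecies <- function(panel) panel@species

#' @rdname panelSequences
#' @export
panelArea <- function(panel) panel@area

#' @rdname panelSequences
#' @export
fragments <- function(panel) panel@fragments

#' @rdname panelSequences
#' @export
alignmentLength <- function(panel) {
  if (length(panel@sequences) == 0L) return(0L)
  Biostrings::width(panel@sequences)[1L]
}

#' @rdname panelSequences
#' @export
panelAnchor <- function(panel) panel@anchor

#' @describeIn ReferencePanel Compact display of a panel.
#' @export
setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel with", length(object), "sequences of",
      alignmentLength(object), "aligned columns\n")
  tab <- table(object@species)
  cat("  species:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (length(object@fragments)) {
    fr <- sprintf("%s [%d-%d]", names(object@fragments),
                  IRanges::start(object@fragments),
                  IRanges::end(object@fragments))
    cat("  fragments:", paste(fr, collapse = ", "), "\n")
  }
  if (length(object@anchor))
    cat("  anchor:", object@anchor$genome, object@anchor$start, "-",
        object@anchor$end, "\n")
  invisible(object)
})

#' @describeIn GLMMFit Compact display of a fit.
#' @export
setMethod("show", "GLMMFit", function(object) {
  cat("Poisson GLMM fit (",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  log-likelihood:", format(object@logLik, digits = 6),
      " parameters:", object@npar, "\n")
  cat("  fixed effects:", length(object@fixef),
      " variance components:", length(object@vcomp), "\n")
  invisible(object)
})
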