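## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
PANEL_ALPHABET <- c(DNA_BASES, "N", "-")

## Round half away from zero to `digits` decimals (base round() rounds half to
## even, which does not reproduce the printed percentages).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Coerce a sequence (character scalar, character vector of bases, DNAString)
## to an upper-case character vector of single characters.
.asChars <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (is.character(x) && length(x) == 1L && nchar(x) != 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(as.character(x))
}

## Character matrix (records x columns) from a panel's sequences.
.panelMatrix <- function(panel) {
  m <- as.matrix(panelSequences(panel))
  toupper(m)
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## sample() that never treats a length-1 pool as 1:n.
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

## Vector of fragment columns for a named fragment of a panel.
.fragmentColumns <- function(panel, fragment) {
  fr <- fragments(panel)
  if (!fragment %in% names(fr))
    stop("unknown fragment '", fragment, "'", call. = FALSE)
  i <- match(fragment, names(fr))
  seq.int(IRanges::start(fr)[i], IRanges::end(fr)[i])
}
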