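#' Load the packaged study-outcome fixtures
#'
#' Two CSV transcriptions of the published study tables ship with the
#' package: the sampling design (one row per specimen per processing level,
#' with the fragment that amplified, `"na"` for failures) and the list of
#' samples that were genetically misidentified or fell below the 98%
#' similarity threshold (one row per listed sample, with the identified
#' species set and similarity).
#'
#' @return List of class `StudyFixture` with elements `sampling` and
#'   `misidentified` (data frames).
#' @export
loadStudyFixtures <- function() {
  f1 <- system.file("extdata", "table1_sampling.csv", package = "cantrace")
  f2 <- system.file("extdata", "table2_misidentified.csv", package = "cantrace")
  if (!nzchar(f1) || !nzchar(f2))
    stop("integrity error: packaged fixtures not found", call. = FALSE)
  sampling <- utils::read.csv(f1, stringsAsFactors = FALSE)
  misid <- utils::read.csv(f2, stringsAsFactors = FALSE)
  nInd <- nrow(unique(sampling[, c("code", "ocean", "specimen")]))
  if (nInd * length(unique(sampling$level)) != nrow(sampling))
    stop("integrity error: sampling fixture is not individuals x levels",
         call. = FALSE)
  if (anyDuplicated(misid$sample_id))
    stop("integrity error: duplicated sample id in misidentification fixture",
         call. = FALSE)
  structure(list(sampling = sampling, misidentified = misid),
            class = "StudyFixture")
}

#' Outcome table implied by the study fixtures
#'
#' Joins the sampling design with the misidentification list: every
#' sequenced record absent from that list was concordant; listed records are
#' MISIDENTIFIED when the best similarity met the threshold (ties included
#' under the strict bookkeeping) and AMBIGUOUS below it; `"na"` records are
#' FAILED.
#'
#' @param fixtures A `StudyFixture` from [loadStudyFixtures()].
#' @param threshold Similarity threshold in percent (default 98).
#' @return `data.frame` with `sample_id, species_label, ocean, level,
#'   fragment, best_identity, species_set, outcome`.
#' @export
studyOutcomes <- function(fixtures = loadStudyFixtures(), threshold = 98) {
  s <- fixtures$sampling
  m <- fixtures$misidentified
  out <- data.frame(
    sample_id = sprintf("%s-%s-%s-%d", s$code, s$ocean, s$level, s$specimen),
    species_label = s$species, ocean = s$ocean, level = s$level,
    fragment = s$fragment, stringsAsFactors = FALSE)
  out$best_identity <- NA_real_
  out$species_set <- NA_character_
  out$outcome <- ifelse(out$fragment == "na", "FAILED", "CONCORDANT")
  idx <- match(m$sample_id, out$sample_id)
  if (anyNA(idx))
    stop("integrity error: misidentified sample(s) not in the design: ",
         paste(m$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  bad <- m$fragment != out$fragment[idx]
  if (any(bad))
    stop("integrity error: fragment mismatch for ",
         paste(m$sample_id[bad], collapse = ", "), call. = FALSE)
  out$best_identity[idx] <- m$similarity
  out$species_set[idx] <- m$identification
  out$outcome[idx] <- ifelse(m$similarity < threshold, "AMBIGUOUS",
                             "MISIDENTIFIED")
  out
}
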