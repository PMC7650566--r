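#' Read a study written by [writeStudy()]
#'
#' Rebuilds the processed-record table from a per-level FASTA directory and
#' its `manifest.csv`.
#'
#' @param dir Directory containing `manifest.csv` and `<level>.fasta` files.
#' @return Study `data.frame` (the [simulateStudy()] shape, without truth
#'   substitution columns).
#' @export
readStudy <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest$sequence <- NA_character_
  for (lv in unique(manifest$level)) {
    path <- file.path(dir, paste0(lv, ".fasta"))
    if (!file.exists(path)) next
    seqs <- Biostrings::readDNAStringSet(path)
    key <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[`, "", 1L)
    idx <- match(key, manifest$individual[manifest$level == lv])
    rows <- which(manifest$level == lv)[idx]
    manifest$sequence[rows] <- as.character(seqs)
  }
  manifest
}

.writeManifest <- function(out, subcommand, seed, config) {
  manifest <- list(
    subcommand = subcommand, seed = seed,
    package = as.character(utils::packageVersion("cantrace")),
    r_version = as.character(getRversion()),
    config = config)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

#' Run one step of the traceability pipeline
#'
#' A thin orchestration layer over the package's functions, mirroring the
#' analysis flow: `simulate` a study (panel + degraded specimens), `gap`
#' analysis of a panel, `identify` specimens against the panel, `ns`
#' accounting, `glmm` inference on the counts, and `report` (concordance
#' and misidentification tables; with `config$fixtures = TRUE` these come
#' from the packaged study tables instead of a run directory).  Every
#' subcommand writes its CSV/JSON outputs plus a `run_manifest.json`
#' echoing the seed and configuration.
#'
#' @param subcommand One of `"simulate"`, `"gap"`, `"identify"`, `"ns"`,
#'   `"glmm"`, `"report"`.
#' @param out Output (and, for downstream steps, input) directory.
#' @param seed Integer seed used by the stochastic steps.
#' @param config Optional named list: `alignment`/`metadata` panel paths for
#'   `gap`/`identify`, `threshold` (default 98), `X` (relative gap width,
#'   default 1.5), `fixtures` (logical, `report`), plus overrides passed to
#'   [panelSpec()], [studyDesign()] and [degradationParams()] fields for
#'   `simulate`.
#' @return Invisibly, a list of the objects the step produced.
#' @export
runPipeline <- function(subcommand, out = ".", seed = 1L, config = list()) {
  subcommands <- c("simulate", "gap", "identify", "ns", "glmm", "report")
  if (length(subcommand) != 1L || !subcommand %in% subcommands)
    stop("usage error: subcommand must be one of ",
         paste(subcommands, collapse = ", "), call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  threshold <- config$threshold %||% 98
  loadRunPanel <- function() {
    al <- config$alignment %||% file.path(out, "panel.fasta")
    md <- config$metadata %||% file.path(out, "panel.csv")
    if (!file.exists(al) || !file.exists(md))
      stop("usage error: panel files not found (", al, ", ", md, ")",
           call. = FALSE)
    loadPanel(al, md)
  }

  res <- switch(subcommand,
    simulate = {
      spec <- panelSpec(seed = seed)
      syn <- synthesizePanel(spec)
      study <- simulateStudy(studyDesign(), syn$panel,
                             degradationParams(), syn$diagnostics,
                             seed = seed + 1L)
      writePanel(syn$panel, file.path(out, "panel.fasta"),
                 file.path(out, "panel.csv"))
      writeStudy(study, out)
      list(panel = syn$panel, study = study)
    },
    gap = {
      panel <- loadRunPanel()
      summary <- barcodeGapSummary(panel, X = config$X %||% 1.5)
      utils::write.csv(distanceTable(panel),
                       file.path(out, "distance_table.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(diagnosticTable(panel, fragment = "B"),
                       file.path(out, "diagnostic_positions.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(unclass(summary),
                           file.path(out, "gap_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(summary = summary)
    },
    identify = {
      panel <- loadRunPanel()
      study <- readStudy(config$study %||% out)
      ids <- identifyStudy(study, panel, threshold = threshold)
      utils::write.csv(ids, file.path(out, "identifications.csv"),
                       row.names = FALSE, quote = FALSE)
      list(identifications = ids)
    },
    ns = {
      study <- readStudy(config$study %||% out)
      ns <- nsTable(study)
      utils::write.csv(ns, file.path(out, "ns_records.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(groupMeanNS(ns, by = c("level", "area", "species_label")),
                       file.path(out, "ns_group_means.csv"),
                       row.names = FALSE, quote = FALSE)
      list(ns = ns)
    },
    glmm = {
      ns <- utils::read.csv(file.path(out, "ns_records.csv"),
                            stringsAsFactors = FALSE)
      full <- fitPoissonGLMM(ns)
      reduced <- fitPoissonGLMM(ns, fixed = nNS ~ level + species)
      lrt <- likelihoodRatioTest(full, reduced)
      od <- overdispersion(full)
      jsonlite::write_json(list(
        fixef = as.list(full@fixef), vcomp = as.list(full@vcomp),
        logLik = full@logLik, npar = full@npar,
        converged = full@converged,
        lrt = unclass(lrt), overdispersion = unclass(od)),
        file.path(out, "glmm.json"), auto_unbox = TRUE, digits = NA)
      list(full = full, reduced = reduced, lrt = lrt, overdispersion = od)
    },
    report = {
      outcomes <- if (isTRUE(config$fixtures)) studyOutcomes(threshold = threshold)
        else utils::read.csv(file.path(out, "identifications.csv"),
                             stringsAsFactors = FALSE)
      writeReport(outcomes, out)
      list(outcomes = outcomes)
    })
  .writeManifest(out, subcommand, seed, config)
  invisible(res)
}

#' Write the concordance report and misidentification list
#'
#' @param outcomes Outcome table (from [identifyStudy()] or
#'   [studyOutcomes()]): needs `fragment`, `level`, `outcome`, and for the
#'   misidentification list `best_identity`, `species_set` plus an id column.
#' @param dir Destination directory.
#' @return Invisibly, the written paths.
#' @export
writeReport <- function(outcomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conc <- concordanceTable(outcomes, by = c("fragment", "level"))
  conc$percent_concordant <- sprintf("%.2f", conc$percent_concordant)
  p1 <- file.path(dir, "concordance.csv")
  utils::write.csv(conc, p1, row.names = FALSE, quote = FALSE)
  mis <- outcomes[outcomes$outcome %in% c("MISIDENTIFIED", "AMBIGUOUS"), ,
                  drop = FALSE]
  id <- mis$sample_id %||% mis$individual %||% rep(NA_character_, nrow(mis))
  lst <- data.frame(
    Level = mis$level %||% character(nrow(mis)),
    Species = mis$species_label %||% character(nrow(mis)),
    Ocean = mis$ocean %||% mis$area %||% rep(NA_character_, nrow(mis)),
    `Sample ID` = id,
    Fragment = mis$fragment,
    Identification = mis$species_set,
    Similarity = sprintf("%.2f", as.numeric(mis$best_identity)),
    check.names = FALSE, stringsAsFactors = FALSE)
  p2 <- file.path(dir, "misidentified.csv")
  utils::write.csv(lst, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
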