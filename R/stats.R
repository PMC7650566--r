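#' Fit a Poisson GLMM to substitution counts
#'
#' Fits `nNS ~ Level * Species` (or a caller-supplied fixed-effect formula)
#' with nested random intercepts by maximum likelihood under a log link,
#' using the Laplace approximation.  The default random structure is the
#' literal `(1 | Individual/Species)` nesting -- intercepts for `individual`
#' and `individual:species`.  When each individual belongs to exactly one
#' species the two terms are confounded and the estimable variance is
#' effectively a single per-individual component; both estimated components
#' are reported.  Treatment coding is used with the first level (`L1`) and
#' the alphabetically first species as references.
#'
#' @param records `data.frame` with columns `individual`, `species`, `level`
#'   and non-negative integer `nNS` (accepts `species_label` / `species_truth`
#'   as the species column).
#' @param fixed Fixed-effects formula (default `nNS ~ level * species`).
#' @param random Random-intercept specification: `"individual/species"`
#'   (default, the literal nesting), `"species/individual"`, `"individual"`,
#'   or `"none"` for a fixed-effects-only Poisson regression.
#' @param nAGQ Integration accuracy passed to [lme4::glmer()]: 1 (default)
#'   is the Laplace approximation; 0 uses the faster penalized-IRLS
#'   approximation, adequate for large simulation studies.
#' @return A [GLMMFit].  The convergence flag is `FALSE` for degenerate
#'   responses (all counts equal) and optimizer failures.
#' @export
fitPoissonGLMM <- function(records, fixed = nNS ~ level * species,
                           random = c("individual/species",
                                      "species/individual",
                                      "individual", "none"),
                           nAGQ = 1L) {
  random <- match.arg(random)
  df <- as.data.frame(records)
  if (is.null(df$species)) {
    spcol <- intersect(c("species_label", "species_truth"), names(df))
    if (length(spcol)) df$species <- df[[spcol[1L]]]
  }
  need <- c("individual", "species", "level", "nNS")
  if (!all(need %in% names(df)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  df <- df[!is.na(df$nNS), , drop = FALSE]
  if (any(df$nNS < 0) || any(df$nNS != round(df$nNS)))
    stop("data error: counts must be non-negative integers", call. = FALSE)
  if (anyDuplicated(df[, c("individual", "level")]))
    stop("data error: duplicated (individual, level) record", call. = FALSE)
  df$level <- factor(df$level)
  df$species <- factor(df$species)
  df$individual <- factor(df$individual)

  reTerm <- switch(random,
    "individual/species" = "(1 | individual/species)",
    "species/individual" = "(1 | species/individual)",
    "individual" = "(1 | individual)",
    "none" = NULL)
  degenerate <- length(unique(df$nNS)) < 2L
  converged <- TRUE

  if (is.null(reTerm)) {
    fit <- suppressWarnings(stats::glm(fixed, family = stats::poisson(), data = df))
    fixef <- stats::coef(fit)
    fixef <- fixef[!is.na(fixef)]
    vcomp <- numeric()
    ll <- as.numeric(stats::logLik(fit))
    converged <- fit$converged && !degenerate
    model <- fit
  } else {
    form <- stats::update(fixed, paste(". ~ . +", reTerm))
    model <- tryCatch(
      withCallingHandlers(
        lme4::glmer(form, family = stats::poisson(), data = df, nAGQ = nAGQ),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(model, "error")) {
      if (!degenerate)
        stop("GLMM fit failed: ", conditionMessage(model), call. = FALSE)
      ## constant response: report the fixed-effects-only fit, flagged
      model <- suppressWarnings(stats::glm(fixed, family = stats::poisson(),
                                           data = df))
      return(new("GLMMFit",
                 fixef = stats::coef(model)[!is.na(stats::coef(model))],
                 vcomp = numeric(), logLik = as.numeric(stats::logLik(model)),
                 npar = length(stats::coef(model)[!is.na(stats::coef(model))]),
                 converged = FALSE, model = model, records = df))
    }
    fixef <- lme4::fixef(model)
    vc <- lme4::VarCorr(model)
    vcomp <- vapply(vc, function(v) as.numeric(v[1L, 1L]), numeric(1L))
    names(vcomp) <- names(vc)
    ll <- as.numeric(stats::logLik(model))
    if (degenerate) converged <- FALSE
    conv <- model@optinfo$conv$opt
    if (!is.null(conv) && conv != 0) converged <- FALSE
  }

  new("GLMMFit",
      fixef = fixef, vcomp = vcomp, logLik = ll,
      npar = length(fixef) + length(vcomp),
      converged = isTRUE(converged), model = model, records = df)
}

#' Standard errors of the fixed effects of a fit
#'
#' @param fit A [GLMMFit].
#' @return Named numeric vector of standard errors (Wald, from the inverse
#'   curvature of the objective at the optimum).
#' @export
fixefSE <- function(fit) {
  v <- as.matrix(stats::vcov(fit@model))
  se <- sqrt(diag(v))
  names(se) <- names(fit@fixef)
  se
}

#' Likelihood-ratio test between nested fits
#'
#' `statistic = 2 * (logLik(full) - logLik(reduced))`, referred to a
#' chi-square distribution with degrees of freedom equal to the difference
#' in estimated parameter counts.  For the study formula -- interaction
#' versus additive with 5 processing levels and 4 species -- the df is
#' `(5 - 1) * (4 - 1) = 12`.
#'
#' @param full,reduced [GLMMFit] objects on the same data, `reduced` nested
#'   in `full`.
#' @return List of class `LRTResult`: `statistic`, `df`, `p_value`.
#' @export
likelihoodRatioTest <- function(full, reduced) {
  df <- full@npar - reduced@npar
  stat <- 2 * (full@logLik - reduced@logLik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  if (df < 0L || (df == 0L && stat > 1e-6))
    stop("nesting error: full model must nest the reduced model",
         call. = FALSE)
  if (stat < 0)
    warning("negative LRT statistic: models may not be nested or fits not converged")
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "LRTResult")
}

#' @exportS3Method base::print
print.LRTResult <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi-square(%d) = %.3f, p = %.3g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Overdispersion estimate for a Poisson fit
#'
#' Ratio of the sum of squared Pearson residuals to the residual degrees of
#' freedom (`n` observations minus the number of estimated parameters, fixed
#' effects plus variance components), with an upper-tail chi-square p-value.
#' A ratio well above 1 signals extra-Poisson variance.
#'
#' @param fit A [GLMMFit].
#' @return List of class `OverdispersionResult`: `ratio`, `residual_df`,
#'   `chisq` (the Pearson statistic), `p_value`.
#' @export
overdispersion <- function(fit) {
  mu <- stats::fitted(fit@model)
  y <- fit@records$nNS
  if (length(mu) != length(y))
    stop("fitted values and records do not align", call. = FALSE)
  if (any(mu == 0 & y > 0))
    stop("residual-domain error: fitted mean 0 with positive count",
         call. = FALSE)
  r <- (y - mu) / sqrt(pmax(mu, .Machine$double.eps))
  rdf <- length(y) - fit@npar
  chisq <- sum(r^2)
  structure(list(ratio = chisq / rdf, residual_df = rdf, chisq = chisq,
                 p_value = stats::pchisq(chisq, rdf, lower.tail = FALSE)),
            class = "OverdispersionResult")
}

#' @exportS3Method base::print
print.OverdispersionResult <- function(x, ...) {
  cat(sprintf("Overdispersion: ratio = %.3f on %d residual df (p = %.3g)\n",
              x$ratio, x$residual_df, x$p_value))
  invisible(x)
}
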