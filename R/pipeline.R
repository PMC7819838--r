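## End-to-end orchestration: simulate -> tables -> bouts -> fits -> reports.
## Reports are plain lists, serialised as JSON with the seed, a config hash
## and the package version embedded so reruns are byte-identical.

reportHeader <- function(configLike, seed) {
  list(package = "neosleep",
       version = as.character(utils::packageVersion("neosleep")),
       seed = seed,
       config_hash = rlang::hash(configLike))
}

fitResultReport <- function(fit) {
  list(family = fit@family,
       params = as.list(fit@params),
       coefficients = as.list(fit@coefficients),
       se = as.list(fit@se),
       loglik = fit@loglik, aic = fit@aic,
       n_bouts = fit@nBouts, n_events = fit@nEvents,
       centering = as.list(fit@centering))
}

#' Fit and rank duration laws for each modelled state
#'
#' For every requested state: Kaplan-Meier curve, censored AFT fits of all
#' candidate families, AIC ranking with deltas, tail classification of the
#' winner, and acceleration factors with Wald 95% CIs for every covariate.
#' States with no observed offset are skipped with a warning.
#'
#' @param input a [BoutSet-class], a list of [Hypnogram-class] objects, or
#'   the cohort list returned by [simulateCohort()].
#' @param statesToFit states to model (default `W`, `AS`, `QS`).
#' @param families candidate duration-law families.
#' @param covariateNames AFT covariates (see [fitFamily()]); use
#'   `character(0)` for covariate-free fits.
#' @param outDir optional output directory for `fit_report.json` and
#'   per-state `curves_<state>.csv`.
#' @param seed seed recorded in the report (the fit itself is
#'   deterministic).
#' @return report list: one element per fitted state plus a `meta` header.
#' @export
runFit <- function(input, statesToFit = modelledStates(),
                   families = familyNames(),
                   covariateNames = c("pma_weeks"),
                   outDir = NULL, seed = NULL) {
  bset <- resolveBoutSet(input)
  b <- bouts(bset)
  report <- list(meta = c(reportHeader(list(statesToFit, families, covariateNames), seed),
                          list(transition_table = as.data.frame.matrix(transitionTable(bset)))))
  curves <- list()
  for (s in statesToFit) {
    bs <- b[b$state == s, , drop = FALSE]
    if (!nrow(bs) || sum(bs$event_observed) == 0) {
      warning("state ", s, ": no observed bout offsets; skipped")
      next
    }
    km <- kmEstimate(bs$duration_min, bs$event_observed)
    fits <- list()
    for (fam in families) {
      ft <- tryCatch(fitFamily(fam, bs, covariateNames = covariateNames),
                     error = function(e) {
                       warning("state ", s, ", ", fam, ": ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(ft)) fits[[fam]] <- ft
    }
    if (!length(fits)) next
    sel <- selectModel(unname(fits))
    best <- sel$fits[[1]]
    factors <- lapply(setNames(nm = names(best@coefficients)),
                      function(nm) as.list(accelerationFactor(best, nm)))
    grid <- seq(0, max(bs$duration_min) * 1.2, length.out = 200)
    fitCurve <- fittedSurvival(
      best, covariateValues = best@centering, times = grid)
    curves[[s]] <- rbind(as.data.frame(km), as.data.frame(fitCurve))
    report[[s]] <- list(
      n_bouts = nrow(bs), n_events = sum(bs$event_observed),
      ranking = sel$ranking,
      best = fitResultReport(best),
      tail_class = classifyTail(best),
      acceleration_factors = factors)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (s in names(curves))
      write.csv(curves[[s]], file.path(outDir, sprintf("curves_%s.csv", s)),
                row.names = FALSE)
  }
  invisible(report)
}

resolveBoutSet <- function(input) {
  if (is(input, "BoutSet")) return(input)
  if (is.list(input) && !is.null(input$hypnograms))
    return(extractCohortBouts(input$hypnograms))
  if (is.list(input) && all(vapply(input, is, TRUE, "Hypnogram")))
    return(extractCohortBouts(input))
  stop("input must be a BoutSet, a list of Hypnograms, or a simulated cohort")
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [simulateCohort()] and [writeCohort()]: emits the
#' epoch, covariate and event tables plus `truth.json` (the generating
#' [SimConfig-class]) and `meta.json` under `outDir`.
#'
#' @param config a [SimConfig-class].
#' @param nSubjects cohort size.
#' @param outDir output directory.
#' @param seed master seed.
#' @param covariateSampler per-subject covariate sampler.
#' @return the simulated cohort list, invisibly.
#' @export
runSimulate <- function(config, nSubjects, outDir, seed = 1,
                        covariateSampler = defaultCovariateSampler) {
  coh <- simulateCohort(config, nSubjects, seed = seed,
                        covariateSampler = covariateSampler)
  writeCohort(coh$hypnograms, outDir)
  writeSimConfig(config, file.path(outDir, "truth.json"))
  jsonlite::write_json(reportHeader(config, seed),
                       file.path(outDir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(coh)
}

#' Sensory-perturbation window report
#'
#' Splits the cohort at a postmenstrual-age threshold and, per age group
#' and event kind, cross-classifies observed state transitions (awakening
#' versus sleep-to-sleep) by whether they fall in the `[0, windowMin)`
#' window after an event, runs the likelihood-ratio (G) association test
#' with Cramer's V, and summarises latencies to awakening (count, median,
#' adjusted Fisher-Pearson skewness). Event kinds absent from the cohort
#' are omitted with a warning; a cohort without events yields an empty
#' report.
#'
#' @param input as in [runFit()].
#' @param eventTable optional data.frame per [sensoryEvents()]; defaults to
#'   the events carried by the hypnograms (required when `input` is a bare
#'   [BoutSet-class]).
#' @param windowMin window length in minutes.
#' @param pmaSplit age threshold in weeks: `older` is `>= pmaSplit`.
#' @param kinds event kinds to analyse.
#' @param outDir optional directory for `perturbation_report.json`.
#' @param seed seed recorded in the report.
#' @return report list with a `perturbation` element (one entry per age
#'   group x event kind) and a `meta` header.
#' @export
runPerturbation <- function(input, eventTable = NULL, windowMin = 5,
                            pmaSplit = 34, kinds = c("lance", "non_noxious"),
                            outDir = NULL, seed = NULL) {
  bset <- resolveBoutSet(input)
  if (is.null(eventTable)) {
    if (is.list(input) && !is.null(input$hypnograms))
      eventTable <- sensoryEvents(input$hypnograms)
    else if (is.list(input) && !is(input, "BoutSet"))
      eventTable <- sensoryEvents(input)
    else stop("eventTable required when input carries no events")
  }
  trans <- transitionEvents(bset)
  report <- list(meta = c(reportHeader(list(windowMin, pmaSplit, kinds), seed),
                          list(window_min = windowMin, pma_split = pmaSplit)),
                 perturbation = list())
  if (!nrow(eventTable) || !nrow(trans)) return(invisible(report))
  groups <- list(younger = trans$pma_weeks < pmaSplit,
                 older = trans$pma_weeks >= pmaSplit)
  for (kind in kinds) {
    if (!any(eventTable$kind == kind)) {
      warning("no events of kind '", kind, "'; omitted")
      next
    }
    for (g in names(groups)) {
      tg <- trans[groups[[g]], , drop = FALSE]
      if (!nrow(tg)) next
      counts <- windowCounts(tg, eventTable, kind = kind, windowMin = windowMin)
      assoc <- tryCatch(associationTest(counts), error = function(e) NULL)
      lat <- tryCatch(
        latenciesToTransition(tg[tg$transition_class == "awakening", , drop = FALSE],
                              eventTable, kind = kind),
        error = function(e) numeric(0))
      skew <- if (length(lat) >= 3 && stats::var(lat) > 0) latencySkewness(lat) else NA_real_
      report$perturbation[[paste(g, kind, sep = "_")]] <- list(
        group = g, kind = kind,
        counts = as.data.frame.matrix(counts),
        g_test = assoc,
        latency = list(n = length(lat),
                       median_min = if (length(lat)) stats::median(lat) else NA_real_,
                       skewness = skew))
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "perturbation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
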