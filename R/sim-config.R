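## Simulator configuration. The defaults are the fitted neonatal sleep
## architecture: lognormal wake and active-sleep durations, Weibull quiet
## sleep, the observed offset-destination proportions, multiplicative
## per-week PMA effects centered at 35 weeks, a cortisol effect on wake,
## and a longer active-sleep law when the bout is destined for quiet sleep.

#' Build a semi-Markov simulator configuration
#'
#' All arguments default to the fitted sleep-architecture estimates:
#' duration laws W ~ lognormal(3.187, 0.996), AS ~ lognormal(4.137, 0.891)
#' (minutes, destination wakefulness), QS ~ Weibull(shape 2.181, scale
#' 34.243 min); offset destinations AS -> QS with probability 49/75 (else
#' W), QS -> AS with 117/118 (else W), W -> AS always; per-week PMA
#' duration multipliers 1.146 (W), 0.945 (AS), 1.027 (QS); wake multiplier
#' 1.335 per microgram/10 dL cortisol; active-sleep multiplier 1.602 when
#' destined for quiet sleep; recording length uniform on 44-70 minutes
#' (the observed interquartile range). Heel lances are scheduled for a
#' random subset of subjects and can truncate an ongoing active-sleep bout
#' into an awakening within 5 minutes, only at >= 34 weeks PMA.
#'
#' @param durationLaws named list (`W`, `AS`, `QS`) of
#'   `list(family =, params =)`.
#' @param transitionProbs 3x3 row-stochastic matrix over `W`, `AS`, `QS`.
#' @param pmaFactors named per-state per-week duration multipliers.
#' @param cortisolFactorW wake multiplier per microgram/10 dL cortisol.
#' @param nextstateFactorAS AS multiplier when destined for QS.
#' @param tsInsertion `list(prob, meanlog, sdlog)` transitional-sleep filler.
#' @param recordingRange recording-length range in minutes.
#' @param lanceSchedule `list(prob_lance, prob_non_noxious)` per subject.
#' @param awakeningTrigger `list(prob, pma_min_weeks, latency_rate)`.
#' @param pmaCenter,cortisolCenter covariate reference values.
#' @param epochLength epoch length in seconds.
#' @return a validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig()
#' expectedOccupancy(cfg, list(pma_weeks = 30))
simConfig <- function(
  durationLaws = list(
    W  = list(family = "lognormal", params = c(meanlog = 3.187, sdlog = 0.996)),
    AS = list(family = "lognormal", params = c(meanlog = 4.137, sdlog = 0.891)),
    QS = list(family = "weibull",   params = c(shape = 2.181, scale = 34.243))
  ),
  transitionProbs = defaultTransitionProbs(),
  pmaFactors = c(W = 1.146, AS = 0.945, QS = 1.027),
  cortisolFactorW = 1.335,
  nextstateFactorAS = 1.602,
  tsInsertion = list(prob = 0.3, meanlog = log(1.5), sdlog = 0.5),
  recordingRange = c(44, 70),
  lanceSchedule = list(prob_lance = 102 / 175, prob_non_noxious = 135 / 175),
  awakeningTrigger = list(prob = 0.35, pma_min_weeks = 34, latency_rate = 0.6),
  pmaCenter = 35, cortisolCenter = 0.2, epochLength = 30) {
  new("SimConfig",
      durationLaws = durationLaws, transitionProbs = transitionProbs,
      pmaFactors = pmaFactors[modelledStates()],
      cortisolFactorW = cortisolFactorW,
      nextstateFactorAS = nextstateFactorAS, tsInsertion = tsInsertion,
      recordingRange = recordingRange, lanceSchedule = lanceSchedule,
      awakeningTrigger = awakeningTrigger, pmaCenter = pmaCenter,
      cortisolCenter = cortisolCenter, epochLength = epochLength)
}

#' @rdname simConfig
#' @export
defaultTransitionProbs <- function() {
  st <- modelledStates()
  P <- matrix(0, 3, 3, dimnames = list(st, st))
  P["W", "AS"] <- 1
  P["AS", "QS"] <- 49 / 75; P["AS", "W"] <- 26 / 75
  P["QS", "AS"] <- 117 / 118; P["QS", "W"] <- 1 / 118
  P
}

#' Read / write a SimConfig as YAML or JSON
#'
#' The file format mirrors the slot structure; the extension picks the
#' serialisation (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @param config a [SimConfig-class].
#' @return `readSimConfig()`: a [SimConfig-class]; `writeSimConfig()`:
#'   `path`, invisibly.
#' @export
readSimConfig <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  laws <- lapply(x$durationLaws, function(l)
    list(family = l$family, params = unlist(l$params)))
  P <- matrix(unlist(x$transitionProbs), 3, 3, byrow = TRUE,
              dimnames = list(modelledStates(), modelledStates()))
  simConfig(
    durationLaws = laws, transitionProbs = P,
    pmaFactors = unlist(x$pmaFactors),
    cortisolFactorW = x$cortisolFactorW,
    nextstateFactorAS = x$nextstateFactorAS,
    tsInsertion = x$tsInsertion,
    recordingRange = unlist(x$recordingRange),
    lanceSchedule = x$lanceSchedule,
    awakeningTrigger = x$awakeningTrigger,
    pmaCenter = x$pmaCenter, cortisolCenter = x$cortisolCenter,
    epochLength = x$epochLength)
}

#' @rdname readSimConfig
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  x <- list(
    durationLaws = lapply(config@durationLaws, function(l)
      list(family = l$family, params = as.list(l$params))),
    transitionProbs = apply(config@transitionProbs, 1, as.list, simplify = FALSE),
    pmaFactors = as.list(config@pmaFactors),
    cortisolFactorW = config@cortisolFactorW,
    nextstateFactorAS = config@nextstateFactorAS,
    tsInsertion = config@tsInsertion,
    recordingRange = config@recordingRange,
    lanceSchedule = config@lanceSchedule,
    awakeningTrigger = config@awakeningTrigger,
    pmaCenter = config@pmaCenter, cortisolCenter = config@cortisolCenter,
    epochLength = config@epochLength)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
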