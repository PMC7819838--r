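## Central S4 classes. All durations are in minutes unless a slot name says
## otherwise; epochs are 0-based and intervals half-open [onset, offset).

#' Sleep-wake state vocabulary
#'
#' The four scored neonatal sleep-wake states: `W` (wakefulness), `AS`
#' (active sleep, the REM precursor), `TS` (transitional sleep) and `QS`
#' (quiet sleep, the non-REM precursor). `TS` is scored but never modelled
#' as a bout state; the three modelled states are returned by
#' `modelledStates()`.
#'
#' @return `sleepStates()`: character vector of the four valid labels.
#' @export
#' @examples
#' sleepStates()
#' modelledStates()
sleepStates <- function() c("W", "AS", "TS", "QS")

#' @rdname sleepStates
#' @export
modelledStates <- function() c("W", "AS", "QS")

## ---------------------------------------------------------------------------

#' Hypnogram: an epoch-scored sleep-wake recording
#'
#' One subject's recording, scored in fixed-length epochs (30 s by default)
#' with one state label per epoch, together with timestamped sensory events
#' (heel lance, non-noxious control stimulus, held status) and subject
#' covariates.
#'
#' @slot subjectId character scalar identifier.
#' @slot epochLength epoch length in seconds (default 30).
#' @slot states character vector, one of `sleepStates()` per epoch.
#' @slot events data.frame with columns `time_min` (minutes from recording
#'   start) and `kind` (one of `lance`, `non_noxious`, `held_start`,
#'   `held_end`).
#' @slot covariates named list with elements `pma_weeks` (postmenstrual age,
#'   decimal weeks), `postnatal_age_days`, `risk_high` (0/1) and
#'   `cortisol_ug_dl` (mean salivary cortisol, micrograms/dL; may be `NA`).
#'
#' @seealso [Hypnogram()] constructor, [extractBouts()], [statePercentages()]
#' @export
setClass("Hypnogram",
  representation(
    subjectId = "character",
    epochLength = "numeric",
    states = "character",
    events = "data.frame",
    covariates = "list"
  )
)

setValidity("Hypnogram", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number of seconds")
  if (length(object@states) == 0L) msg <- c(msg, "states must be non-empty")
  bad <- setdiff(unique(object@states), sleepStates())
  if (length(bad))
    msg <- c(msg, sprintf("unknown state code(s): %s", paste(bad, collapse = ", ")))
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("time_min", "kind") %in% names(ev)))
      msg <- c(msg, "events must have columns time_min, kind")
    else {
      total_min <- length(object@states) * object@epochLength / 60
      if (any(ev$time_min < 0 | ev$time_min > total_min))
        msg <- c(msg, "event times must lie within the recording")
      badk <- setdiff(unique(ev$kind), c("lance", "non_noxious", "held_start", "held_end"))
      if (length(badk))
        msg <- c(msg, sprintf("unknown event kind(s): %s", paste(badk, collapse = ", ")))
    }
  }
  cv <- object@covariates
  pma <- cv$pma_weeks
  if (!is.null(pma) && !is.na(pma) && (pma < 22 || pma > 46))
    msg <- c(msg, "pma_weeks outside plausible range [22, 46]")
  cort <- cv$cortisol_ug_dl
  if (!is.null(cort) && !is.na(cort) && cort < 0)
    msg <- c(msg, "cortisol_ug_dl must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param subjectId subject identifier.
#' @param states character vector of epoch state labels (`W`, `AS`, `TS`, `QS`).
#' @param epochLength epoch length in seconds.
#' @param events data.frame of sensory events (`time_min`, `kind`), or `NULL`.
#' @param covariates named list of subject covariates; missing elements are
#'   filled with `NA`.
#' @return a validated [Hypnogram-class] object.
#' @export
#' @examples
#' h <- Hypnogram("s1", c("W", "W", "AS"), covariates = list(pma_weeks = 32))
#' statePercentages(h)
Hypnogram <- function(subjectId, states, epochLength = 30,
                      events = NULL, covariates = list()) {
  if (is.null(events))
    events <- data.frame(time_min = numeric(0), kind = character(0))
  defaults <- list(pma_weeks = NA_real_, postnatal_age_days = NA_real_,
                   risk_high = NA_real_, cortisol_ug_dl = NA_real_)
  covariates <- utils::modifyList(defaults, covariates[!vapply(covariates, is.null, TRUE)])
  new("Hypnogram", subjectId = as.character(subjectId),
      epochLength = epochLength, states = as.character(states),
      events = events, covariates = covariates)
}

## ---------------------------------------------------------------------------

#' BoutSet: censored bout records extracted from hypnograms
#'
#' Container for the survival-analysis substrate: one row per maximal run of
#' a modelled state (`W`, `AS`, `QS`) whose onset transition was observed
#' within the recording. The run at recording start (onset not captured) is
#' kept separately as left-censored and excluded from duration modelling.
#'
#' Both slots are data.frames with columns `subject_id`, `state`,
#' `onset_min`, `duration_min`, `onset_captured`, `event_observed`
#' (1 = offset captured), `next_state` (`NA` when unobserved), plus one
#' column per subject covariate.
#'
#' @slot bouts data.frame of modelled (onset-captured) bouts.
#' @slot leftCensored data.frame of onset-uncaptured first runs.
#' @seealso [extractBouts()], [transitionTable()], [fitFamily()]
#' @export
setClass("BoutSet",
  representation(bouts = "data.frame", leftCensored = "data.frame")
)

setValidity("BoutSet", function(object) {
  msg <- character(0)
  b <- object@bouts
  need <- c("subject_id", "state", "onset_min", "duration_min",
            "onset_captured", "event_observed", "next_state")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("bouts must have columns", paste(need, collapse = ", ")))
  else if (nrow(b)) {
    if (any(!b$state %in% modelledStates()))
      msg <- c(msg, "bout states must be W, AS or QS")
    if (any(b$duration_min < 1 - 1e-9))
      msg <- c(msg, "bout durations must be >= 1 minute")
    ## next_state recorded only when the offset was observed
    if (any(!is.na(b$next_state) & b$event_observed == 0))
      msg <- c(msg, "next_state present for a censored bout")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------

#' SurvivalCurve: a step or smooth survival estimate
#'
#' @slot time ordered times in minutes (first element 0).
#' @slot surv survival probabilities, non-increasing, in [0, 1].
#' @slot lower,upper pointwise confidence band (may be `NA`).
#' @slot kind `"empirical"` (Kaplan-Meier) or `"fitted"` (model-derived).
#' @seealso [kmEstimate()], [fittedSurvival()]
#' @export
setClass("SurvivalCurve",
  representation(time = "numeric", surv = "numeric",
                 lower = "numeric", upper = "numeric", kind = "character")
)

setValidity("SurvivalCurve", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@surv) != n) msg <- c(msg, "time and surv lengths differ")
  if (n && (any(object@surv > 1 + 1e-12) || any(object@surv < -1e-12)))
    msg <- c(msg, "surv outside [0, 1]")
  if (n > 1 && any(diff(object@surv) > 1e-12)) msg <- c(msg, "surv must be non-increasing")
  if (n > 1 && any(diff(object@time) < 0)) msg <- c(msg, "time must be ordered")
  ok <- !is.na(object@lower) & !is.na(object@upper)
  if (any(ok & (object@lower > object@surv + 1e-9 | object@upper < object@surv - 1e-9)))
    msg <- c(msg, "band must contain the point estimate")
  if (!object@kind %in% c("empirical", "fitted")) msg <- c(msg, "kind must be empirical or fitted")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------

#' FitResult: a fitted parametric duration law
#'
#' Result of censored maximum-likelihood fitting of one duration-law family,
#' optionally with accelerated-failure-time (AFT) covariates. Baseline
#' parameters are on the natural scale and refer to a bout at the covariate
#' reference (centering) values; each coefficient is the log duration ratio
#' per unit of the (centered) covariate, so `exp(coef)` is the acceleration
#' factor.
#'
#' @slot family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"powerlaw"`.
#' @slot params named numeric baseline parameters (`rate`; `shape`,`scale`;
#'   `meanlog`,`sdlog`; `exponent` with fixed `xmin` = 1 min).
#' @slot coefficients named numeric AFT log-acceleration coefficients.
#' @slot se named standard errors for baseline parameters and coefficients.
#' @slot vcov variance-covariance matrix on the optimisation scale.
#' @slot loglik maximised censored log-likelihood.
#' @slot aic Akaike information criterion, `2k - 2 loglik`.
#' @slot nBouts,nEvents number of bouts and of observed (uncensored) offsets.
#' @slot centering named covariate reference values subtracted before fitting.
#' @slot dataFingerprint internal hash identifying the fitted bout set, used
#'   to refuse AIC comparison or likelihood-ratio tests across different data.
#' @slot convergence optimiser convergence code (0 = converged).
#' @seealso [fitFamily()], [selectModel()], [classifyTail()],
#'   [accelerationFactor()]
#' @export
setClass("FitResult",
  representation(
    family = "character", params = "numeric", coefficients = "numeric",
    se = "numeric", vcov = "matrix", loglik = "numeric", aic = "numeric",
    nBouts = "integer", nEvents = "integer", centering = "numeric",
    dataFingerprint = "character", convergence = "integer"
  )
)

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (!object@family %in% c("exponential", "weibull", "lognormal", "powerlaw"))
    msg <- c(msg, "unknown family")
  k <- length(object@params) + length(object@coefficients)
  if (abs(object@aic - (2 * k - 2 * object@loglik)) > 1e-6)
    msg <- c(msg, "aic inconsistent with loglik and parameter count")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "negative standard error")
  p <- object@params
  if (object@family == "weibull" && (p[["shape"]] <= 0 || p[["scale"]] <= 0))
    msg <- c(msg, "weibull shape and scale must be positive")
  if (object@family == "lognormal" && p[["sdlog"]] <= 0)
    msg <- c(msg, "lognormal sdlog must be positive")
  if (object@family == "exponential" && p[["rate"]] <= 0)
    msg <- c(msg, "exponential rate must be positive")
  if (object@family == "powerlaw" && p[["exponent"]] <= 1)
    msg <- c(msg, "power-law exponent must exceed 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------

#' SimConfig: parameterization of the semi-Markov hypnogram generator
#'
#' Full specification of the alternating-renewal (semi-Markov) generative
#' model: per-state duration laws, the embedded transition matrix over the
#' modelled states, multiplicative covariate effects on durations,
#' transitional-sleep filler, recording-length law and the nociceptive event
#' schedule. Defaults reproduce the fitted neonatal sleep architecture; see
#' [simConfig()].
#'
#' @slot durationLaws named list (`W`, `AS`, `QS`), each
#'   `list(family =, params =)`.
#' @slot transitionProbs 3x3 row-stochastic matrix over `W`, `AS`, `QS`
#'   (diagonal zero).
#' @slot pmaFactors named per-state duration multipliers per week of
#'   postmenstrual age (centered at `pmaCenter`).
#' @slot cortisolFactorW wake-duration multiplier per microgram/10 dL of
#'   salivary cortisol above `cortisolCenter`.
#' @slot nextstateFactorAS active-sleep duration multiplier when the bout is
#'   destined for quiet sleep rather than wakefulness (destination drawn
#'   before the duration).
#' @slot tsInsertion `list(prob, meanlog, sdlog)`: probability of inserting a
#'   transitional-sleep filler run at a state change, and its lognormal
#'   duration law (minutes).
#' @slot recordingRange `c(min, max)` minutes; recording length drawn
#'   uniformly.
#' @slot lanceSchedule `list(prob_lance, prob_non_noxious)`: per-subject
#'   probability of one heel lance / one non-noxious stimulus at a uniform
#'   random time.
#' @slot awakeningTrigger `list(prob, pma_min_weeks, latency_rate)`:
#'   probability that a lance falling inside an active-sleep bout truncates
#'   it to an awakening, gated at `pma_min_weeks`; the latency from lance to
#'   awakening is exponential with rate `latency_rate` (per minute),
#'   truncated below 5 minutes.
#' @slot pmaCenter,cortisolCenter covariate reference values (35 weeks,
#'   0.2 micrograms/dL).
#' @slot epochLength epoch length in seconds.
#' @seealso [simConfig()], [simulateSubject()], [simulateCohort()]
#' @export
setClass("SimConfig",
  representation(
    durationLaws = "list", transitionProbs = "matrix",
    pmaFactors = "numeric", cortisolFactorW = "numeric",
    nextstateFactorAS = "numeric", tsInsertion = "list",
    recordingRange = "numeric", lanceSchedule = "list",
    awakeningTrigger = "list", pmaCenter = "numeric",
    cortisolCenter = "numeric", epochLength = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  st <- modelledStates()
  if (!all(st %in% names(object@durationLaws)))
    msg <- c(msg, "durationLaws must name W, AS and QS")
  P <- object@transitionProbs
  if (!all(dim(P) == c(3, 3)) || !identical(rownames(P), st) || !identical(colnames(P), st))
    msg <- c(msg, "transitionProbs must be 3x3 with dimnames W, AS, QS")
  else {
    if (any(abs(rowSums(P) - 1) > 1e-8)) msg <- c(msg, "transition rows must sum to 1")
    if (any(diag(P) != 0)) msg <- c(msg, "self-transitions are not allowed")
    if (any(P < 0)) msg <- c(msg, "transition probabilities must be non-negative")
  }
  if (any(object@pmaFactors <= 0) || object@cortisolFactorW <= 0 ||
      object@nextstateFactorAS <= 0)
    msg <- c(msg, "all duration multipliers must be positive")
  for (s in st) {
    law <- object@durationLaws[[s]]
    if (!is.list(law) || is.null(law$family) || is.null(law$params)) {
      msg <- c(msg, sprintf("durationLaws$%s must be list(family=, params=)", s))
    } else {
      chk <- tryCatch({checkFamilyParams(law$family, law$params); NULL},
                      error = function(e) conditionMessage(e))
      if (!is.null(chk)) msg <- c(msg, sprintf("%s law: %s", s, chk))
    }
  }
  if (length(object@recordingRange) != 2L || any(object@recordingRange <= 0) ||
      diff(object@recordingRange) < 0)
    msg <- c(msg, "recordingRange must be increasing positive c(min, max) minutes")
  if (length(msg)) msg else TRUE
})
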