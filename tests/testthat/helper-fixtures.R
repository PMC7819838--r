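## Shared fixtures, built in code.

## rep-shorthand: st("W",4, "AS",10) -> c("W","W",..)
st <- function(...) {
  a <- list(...)
  unlist(lapply(seq(1, length(a), by = 2), function(i) rep(a[[i]], a[[i + 1]])))
}

hyp <- function(states, id = "s1", pma = 35, cortisol = NA_real_, events = NULL) {
  Hypnogram(id, states, events = events,
            covariates = list(pma_weeks = pma, postnatal_age_days = 30,
                              risk_high = 0, cortisol_ug_dl = cortisol))
}

## study-condition config with the sensory-event schedule switched off
## (overridable through ...)
quietConfig <- function(...) {
  args <- list(...)
  if (!"lanceSchedule" %in% names(args))
    args$lanceSchedule <- list(prob_lance = 0, prob_non_noxious = 0)
  do.call(simConfig, args)
}

fixedCovSampler <- function(pma = 35, cortisol = NA_real_) {
  function(n) data.frame(pma_weeks = rep(pma, n), postnatal_age_days = 30,
                         risk_high = 0, cortisol_ug_dl = cortisol)
}

noCortisolSampler <- function(n) {
  data.frame(pma_weeks = runif(n, 28, 40), postnatal_age_days = round(runif(n, 1, 60)),
             risk_high = rbinom(n, 1, 0.3), cortisol_ug_dl = NA_real_)
}

## fabricate a FitResult for unit tests of ranking/classification (values
## need only be internally consistent: aic = 2k - 2 loglik)
fakeFit <- function(family, params, aicVal, coefficients = numeric(0),
                    se = NULL, fingerprint = "shared") {
  k <- length(params) + length(coefficients)
  ll <- (2 * k - aicVal) / 2
  if (is.null(se)) se <- setNames(rep(0.1, k), c(names(params), names(coefficients)))
  new("FitResult", family = family, params = params, coefficients = coefficients,
      se = se, vcov = diag(k) * 0.01, loglik = ll, aic = aicVal,
      nBouts = 100L, nEvents = 80L, centering = numeric(0),
      dataFingerprint = fingerprint, convergence = 0L)
}

## Deterministic fixture reproducing the published window structure: 35
## awakenings of which 10 fall in the 5 minutes after a lance, alongside
## 100 sleep-to-sleep transitions of which 8 fall inside windows.
makePerturbationFixture <- function() {
  events <- data.frame(subject_id = "a", time_min = seq(10, 1060, by = 30),
                       kind = "lance", stringsAsFactors = FALSE)
  tr <- function(times, class) {
    data.frame(subject_id = "a", time_min = times,
               from_state = "AS", to_state = ifelse(class == "awakening", "W", "QS"),
               transition_class = class, pma_weeks = 36, stringsAsFactors = FALSE)
  }
  ## events are 30 min apart, so +2 and +4.9 fall inside the 5-min window
  ## while +16 and +20 fall between windows
  aw_in <- tr(events$time_min[1:10] + 2, "awakening")
  aw_out <- tr(events$time_min[11:35] + 16, "awakening")
  s2s_in <- tr(events$time_min[1:8] + 4.9, "sleep_to_sleep")
  s2s_out <- tr(rep(events$time_min, length.out = 92) + 20, "sleep_to_sleep")
  list(transitions = rbind(aw_in, aw_out, s2s_in, s2s_out), events = events)
}
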