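## Survival-curve estimation: empirical Kaplan-Meier (via the survival
## package) and model-derived curves for graphical goodness-of-fit.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the bout-duration survival function under
#' right-censoring, with the Greenwood-variance pointwise confidence band
#' (log-transformed, the `survfit` default). Time 0 with survival 1 is
#' prepended. A fully censored input yields a flat curve at 1.
#'
#' @param durations bout durations in minutes, positive.
#' @param eventObserved 0/1 vector; 1 when the offset was observed.
#' @param conf.int confidence level for the band.
#' @return a [SurvivalCurve-class] with `kind = "empirical"`.
#' @export
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' as.data.frame(km)  # S = 1, 2/3, 1/3, 0 at t = 0, 1, 2, 3
kmEstimate <- function(durations, eventObserved, conf.int = 0.95) {
  if (!length(durations)) stop("empty input")
  stopifnot(length(durations) == length(eventObserved), all(durations > 0))
  sf <- survival::survfit(survival::Surv(durations, eventObserved) ~ 1,
                          conf.int = conf.int)
  new("SurvivalCurve",
      time = c(0, sf$time), surv = c(1, sf$surv),
      lower = c(1, ifelse(is.na(sf$lower) & sf$surv == 0, 0, sf$lower)),
      upper = c(1, ifelse(is.na(sf$upper) & sf$surv == 0, 0, sf$upper)),
      kind = "empirical")
}

#' Model-derived survival curve
#'
#' Survival function of a fitted duration law, evaluated at given covariate
#' values: the baseline curve is stretched in time by the fitted
#' acceleration `exp(sum(coef * (x - centering)))`.
#'
#' @param fit a [FitResult-class].
#' @param covariateValues named numeric values (on the original, uncentered
#'   scale) for every covariate in the fit; ignored for covariate-free fits.
#' @param times increasing non-negative times in minutes.
#' @return a [SurvivalCurve-class] with `kind = "fitted"` (no band).
#' @export
#' @examples
#' d <- data.frame(duration_min = c(2, 4, 6), event_observed = c(1, 1, 1))
#' f <- fitFamily("exponential", d)
#' fittedSurvival(f, times = c(0, 4))
fittedSurvival <- function(fit, covariateValues = numeric(0), times) {
  stopifnot(is(fit, "FitResult"))
  if (any(times < 0)) stop("negative times")
  if (is.unsorted(times)) stop("times must be increasing")
  loga <- 0
  if (length(fit@coefficients)) {
    nm <- names(fit@coefficients)
    if (!all(nm %in% names(covariateValues)))
      stop("covariateValues must supply: ", paste(nm, collapse = ", "))
    x <- unlist(covariateValues)[nm] - fit@centering[nm]
    loga <- sum(fit@coefficients * x)
  }
  s <- familySurvival(fit@family, fit@params, times / exp(loga))
  new("SurvivalCurve", time = times, surv = pmin(1, s),
      lower = rep(NA_real_, length(times)), upper = rep(NA_real_, length(times)),
      kind = "fitted")
}
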