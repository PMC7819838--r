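## Censored accelerated-failure-time likelihood.
##
## Covariates act multiplicatively on time: a bout with covariate row x has
## duration T = a * T0 with a = exp(beta' x) and T0 following the baseline
## law. An observed offset therefore contributes f(t / a) / a to the
## likelihood and a right-censored bout contributes S(t / a).

#' Negative censored AFT log-likelihood
#'
#' Evaluates the negative log-likelihood of a parametric duration law with
#' accelerated-failure-time covariates over a set of (possibly
#' right-censored) bout durations. With all coefficients zero (or no
#' covariates) this is the plain censored likelihood of the family.
#'
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"powerlaw"`.
#' @param params named baseline parameters of the family.
#' @param durations bout durations in minutes, positive.
#' @param eventObserved 0/1 vector, 1 when the bout offset was observed.
#' @param covariateMatrix numeric matrix (bouts x covariates), already
#'   centered, or `NULL` for no covariates.
#' @param coefficients numeric AFT log-acceleration coefficients, one per
#'   covariate column.
#' @return scalar negative log-likelihood. Out-of-support parameters are an
#'   error, not a silent clip.
#' @seealso [fitFamily()]
#' @export
#' @examples
#' ## exponential closed form: n log(rate) - rate * sum(t), negated
#' negLoglikCensored("exponential", c(rate = 0.25), c(2, 4, 6), c(1, 1, 1))
negLoglikCensored <- function(family, params, durations, eventObserved,
                              covariateMatrix = NULL, coefficients = numeric(0)) {
  checkFamilyParams(family, params)
  stopifnot(length(durations) == length(eventObserved), all(durations > 0))
  loga <- aftLogAcceleration(covariateMatrix, coefficients, length(durations))
  u <- durations / exp(loga)
  ev <- eventObserved == 1
  ll <- sum(familyLogDensity(family, params, u[ev]) - loga[ev]) +
        sum(familyLogSurvival(family, params, u[!ev]))
  if (!is.finite(ll))
    stop("non-finite log-likelihood (parameters at the edge of the support)")
  -ll
}

aftLogAcceleration <- function(covariateMatrix, coefficients, n) {
  if (is.null(covariateMatrix) || length(coefficients) == 0L) return(rep(0, n))
  covariateMatrix <- as.matrix(covariateMatrix)
  stopifnot(nrow(covariateMatrix) == n,
            ncol(covariateMatrix) == length(coefficients))
  drop(covariateMatrix %*% coefficients)
}
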