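## Duration-law families. Four candidate laws for bout durations, of
## increasing right-skew: Weibull (light-tailed when shape > 1),
## exponential, lognormal and a continuous power law (Pareto) with fixed
## lower bound xmin = 1 minute, the minimum scoreable bout. The power law
## competes on AIC like the others; no xmin estimation is performed.

familyNames <- function() c("exponential", "weibull", "lognormal", "powerlaw")

familyParamNames <- function(family) {
  switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    powerlaw = "exponent",
    stop("unknown family: ", family)
  )
}

#' @keywords internal
checkFamilyParams <- function(family, params) {
  nm <- familyParamNames(family)
  params <- unlist(params)
  if (!all(nm %in% names(params)))
    stop(sprintf("%s law needs parameter(s) %s", family, paste(nm, collapse = ", ")))
  p <- params[nm]
  if (any(!is.finite(p))) stop("non-finite parameter")
  bad <- switch(family,
    exponential = p[["rate"]] <= 0,
    weibull = p[["shape"]] <= 0 || p[["scale"]] <= 0,
    lognormal = p[["sdlog"]] <= 0,
    powerlaw = p[["exponent"]] <= 1
  )
  if (bad) stop(sprintf("parameters outside the support of the %s family", family))
  invisible(p)
}

pareto_xmin <- 1  # minutes; the minimum scoreable bout

## log density and log survival, vectorised over t
familyLogDensity <- function(family, params, t) {
  switch(family,
    exponential = dexp(t, rate = params[["rate"]], log = TRUE),
    weibull = dweibull(t, shape = params[["shape"]], scale = params[["scale"]], log = TRUE),
    lognormal = dlnorm(t, meanlog = params[["meanlog"]], sdlog = params[["sdlog"]], log = TRUE),
    powerlaw = {
      a <- params[["exponent"]]
      ifelse(t >= pareto_xmin,
             log(a - 1) + (a - 1) * log(pareto_xmin) - a * log(t), -Inf)
    }
  )
}

familyLogSurvival <- function(family, params, t) {
  switch(family,
    exponential = pexp(t, rate = params[["rate"]], lower.tail = FALSE, log.p = TRUE),
    weibull = pweibull(t, shape = params[["shape"]], scale = params[["scale"]],
                       lower.tail = FALSE, log.p = TRUE),
    lognormal = plnorm(t, meanlog = params[["meanlog"]], sdlog = params[["sdlog"]],
                       lower.tail = FALSE, log.p = TRUE),
    powerlaw = {
      a <- params[["exponent"]]
      ifelse(t >= pareto_xmin, -(a - 1) * (log(t) - log(pareto_xmin)), 0)
    }
  )
}

familySurvival <- function(family, params, t) exp(familyLogSurvival(family, params, t))

familyMean <- function(family, params) {
  switch(family,
    exponential = 1 / params[["rate"]],
    weibull = params[["scale"]] * gamma(1 + 1 / params[["shape"]]),
    lognormal = exp(params[["meanlog"]] + params[["sdlog"]]^2 / 2),
    powerlaw = {
      a <- params[["exponent"]]
      if (a <= 2) Inf else pareto_xmin * (a - 1) / (a - 2)
    }
  )
}

familyDraw <- function(family, params, n) {
  switch(family,
    exponential = rexp(n, rate = params[["rate"]]),
    weibull = rweibull(n, shape = params[["shape"]], scale = params[["scale"]]),
    lognormal = rlnorm(n, meanlog = params[["meanlog"]], sdlog = params[["sdlog"]]),
    powerlaw = pareto_xmin * runif(n)^(-1 / (params[["exponent"]] - 1))
  )
}

## Length-biased ("equilibrium") draws: density t f(t) / E[T]. Used to put
## the generator's first, left-censored run into time stationarity. Closed
## forms: length-biased lognormal(mu, s) is lognormal(mu + s^2, s);
## length-biased Weibull(k, l) is l * G^(1/k) with G ~ Gamma((k+1)/k);
## length-biased exponential(r) is Gamma(2, r). Residual life is then a
## uniform fraction of the length-biased draw.
familyDrawResidual <- function(family, params, n) {
  lb <- switch(family,
    exponential = rgamma(n, shape = 2, rate = params[["rate"]]),
    weibull = {
      k <- params[["shape"]]
      params[["scale"]] * rgamma(n, shape = (k + 1) / k, rate = 1)^(1 / k)
    },
    lognormal = rlnorm(n, meanlog = params[["meanlog"]] + params[["sdlog"]]^2,
                       sdlog = params[["sdlog"]]),
    ## no convenient closed form; a plain draw is adequate for a run that the
    ## extractor discards as left-censored anyway
    powerlaw = familyDraw(family, params, n)
  )
  runif(n) * lb
}

## Optimisation-scale transforms: positive parameters on the log scale,
## lognormal meanlog unconstrained, power-law exponent as log(exponent - 1).
paramsToOpt <- function(family, params) {
  switch(family,
    exponential = c(log_rate = log(params[["rate"]])),
    weibull = c(log_shape = log(params[["shape"]]), log_scale = log(params[["scale"]])),
    lognormal = c(meanlog = params[["meanlog"]], log_sdlog = log(params[["sdlog"]])),
    powerlaw = c(log_exponent_m1 = log(params[["exponent"]] - 1))
  )
}

paramsFromOpt <- function(family, theta) {
  switch(family,
    exponential = c(rate = exp(theta[[1]])),
    weibull = c(shape = exp(theta[[1]]), scale = exp(theta[[2]])),
    lognormal = c(meanlog = theta[[1]], sdlog = exp(theta[[2]])),
    powerlaw = c(exponent = 1 + exp(theta[[1]]))
  )
}

## d(natural)/d(opt) for the delta-method SEs of baseline parameters
paramsJacobianDiag <- function(family, params) {
  switch(family,
    exponential = params[["rate"]],
    weibull = c(params[["shape"]], params[["scale"]]),
    lognormal = c(1, params[["sdlog"]]),
    powerlaw = params[["exponent"]] - 1
  )
}
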