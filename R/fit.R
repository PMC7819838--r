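## Censored maximum-likelihood fitting, AIC ranking, tail classification.

familyOrder <- function() c("exponential", "weibull", "lognormal", "powerlaw")

#' Default covariate centering
#'
#' Reference values subtracted from covariates before fitting, so that
#' baseline parameters describe a bout at a 35-week postmenstrual age,
#' 0.2 microgram/dL cortisol reference. `cortisol_10dl` is the derived
#' cortisol covariate in micrograms/10 dL (i.e. `10 * cortisol_ug_dl`),
#' matching the per-unit scale on which the wake acceleration factor is
#' reported.
#'
#' @return named numeric vector of reference values.
#' @export
defaultCentering <- function() {
  c(pma_weeks = 35, cortisol_ug_dl = 0.2, cortisol_10dl = 2,
    postnatal_age_days = 0, risk_high = 0, dest_qs = 0)
}

## Resolve a covariate matrix from the bout frame; two derived columns are
## understood: cortisol_10dl (= 10 * cortisol_ug_dl) and dest_qs (indicator
## that the observed offset was into quiet sleep).
buildCovariateMatrix <- function(df, covariateNames, centering) {
  if (!length(covariateNames)) return(NULL)
  if (anyDuplicated(covariateNames)) stop("duplicated covariate names")
  cols <- lapply(covariateNames, function(nm) {
    v <- if (nm %in% names(df)) df[[nm]]
         else if (nm == "cortisol_10dl" && "cortisol_ug_dl" %in% names(df))
           10 * df$cortisol_ug_dl
         else if (nm == "dest_qs" && "next_state" %in% names(df))
           as.numeric(!is.na(df$next_state) & df$next_state == "QS")
         else stop("bout records do not supply covariate: ", nm)
    if (anyNA(v)) stop("missing values in covariate: ", nm)
    v - (if (nm %in% names(centering)) centering[[nm]] else 0)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariateNames
  X
}

momentInit <- function(family, t, ev) {
  te <- t[ev == 1]
  switch(family,
    exponential = c(rate = sum(ev) / sum(t)),
    lognormal = {
      s <- stats::sd(log(te))
      c(meanlog = mean(log(te)), sdlog = if (is.finite(s) && s > 0) s else 1)
    },
    weibull = {
      ## rank regression of log(-log S_KM) on log t at observed event times
      km <- survival::survfit(survival::Surv(t, ev) ~ 1)
      keep <- km$n.event > 0 & km$surv > 1e-6 & km$surv < 1 - 1e-6
      if (sum(keep) >= 2) {
        cf <- unname(stats::coef(
          stats::lm(log(-log(km$surv[keep])) ~ log(km$time[keep]))))
        shape <- max(cf[2], 0.05)
        c(shape = shape, scale = exp(-cf[1] / shape))
      } else c(shape = 1, scale = mean(t))
    },
    powerlaw = {
      hill <- sum(log(pmax(te, pareto_xmin) / pareto_xmin))
      c(exponent = if (hill > 0) 1 + length(te) / hill else 2.5)
    }
  )
}

numHessian <- function(fn, x, relStep = 1e-5) {
  p <- length(x)
  h <- relStep * pmax(1, abs(x))
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        e <- rep(0, p); e[i] <- h[i]
        H[i, i] <- (fn(x + e) - 2 * fn(x) + fn(x - e)) / h[i]^2
      } else {
        ei <- rep(0, p); ei[i] <- h[i]
        ej <- rep(0, p); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit a censored AFT duration law
#'
#' Maximises the censored likelihood of one duration-law family over bout
#' records, optionally with accelerated-failure-time covariates
#' (multiplicative on duration; see [negLoglikCensored()]). Positive
#' parameters are optimised on the log scale; initial values are
#' moment-based (closed form for the exponential, log-duration moments for
#' the lognormal, Kaplan-Meier rank regression for the Weibull, Hill
#' estimate for the power law) with three deterministic perturbed restarts
#' on failure, so the fit is reproducible. Standard errors come from the
#' inverse numerical Hessian (central differences) at the optimum.
#'
#' @param family duration-law family name.
#' @param data a [BoutSet-class], or a data.frame with columns
#'   `duration_min` and `event_observed` plus any covariate columns.
#' @param covariateNames covariates to include (AFT log-acceleration per
#'   unit); the derived names `cortisol_10dl` and `dest_qs` are understood.
#' @param state optional single state to filter the bout records to.
#' @param centering named reference values; defaults per [defaultCentering()].
#' @return a [FitResult-class].
#' @seealso [selectModel()], [classifyTail()], [accelerationFactor()]
#' @export
#' @examples
#' d <- data.frame(duration_min = c(2, 4, 6), event_observed = c(1, 0, 1))
#' params(fitFamily("exponential", d))  # events / total time = 2/12
fitFamily <- function(family, data, covariateNames = character(0),
                      state = NULL, centering = defaultCentering()) {
  family <- match.arg(family, familyNames())
  df <- if (is(data, "BoutSet")) bouts(data) else as.data.frame(data)
  if (!is.null(state)) df <- df[df$state == state, , drop = FALSE]
  stopifnot(all(c("duration_min", "event_observed") %in% names(df)))
  t <- df$duration_min
  ev <- as.integer(df$event_observed)
  X <- buildCovariateMatrix(df, covariateNames, centering)
  nPar <- length(familyParamNames(family))
  k <- nPar + length(covariateNames)
  if (length(t) < k + 2)
    stop(sprintf("too few bouts (%d) to fit %d parameters", length(t), k))
  if (sum(ev) == 0) stop("all bouts are censored; the likelihood is unbounded")
  if (family == "powerlaw" && any(t < pareto_xmin))
    stop("power law with x_min = 1 minute cannot explain shorter durations")

  init <- momentInit(family, t, ev)
  theta0 <- c(paramsToOpt(family, init), rep(0, length(covariateNames)))
  obj <- function(theta) {
    pars <- paramsFromOpt(family, theta[seq_len(nPar)])
    beta <- theta[-seq_len(nPar)]
    suppressWarnings(tryCatch(negLoglikCensored(family, pars, t, ev, X, beta),
                              error = function(e) 1e10))
  }

  ## deterministic restart ladder; no RNG is touched during fitting
  jitters <- list(0, 0.5, -0.5, 1.0)
  best <- NULL
  for (j in jitters) {
    opt <- tryCatch(
      optim(theta0 + j, obj, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-14,
                           ndeps = rep(1e-6, length(theta0)))),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        opt$convergence == 0) { best <- opt; break }
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    stop(sprintf("censored %s fit did not converge after restarts (n=%d, events=%d)",
                 family, length(t), sum(ev)))

  theta <- best$par
  pars <- paramsFromOpt(family, theta[seq_len(nPar)])
  names(pars) <- familyParamNames(family)
  beta <- theta[-seq_len(nPar)]
  names(beta) <- covariateNames

  H <- numHessian(obj, theta)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  seOpt <- suppressWarnings(sqrt(diag(V)))
  seNat <- c(abs(paramsJacobianDiag(family, pars)) * seOpt[seq_len(nPar)],
             seOpt[-seq_len(nPar)])
  names(seNat) <- c(names(pars), covariateNames)

  ll <- -best$value
  cen <- vapply(covariateNames,
                function(nm) if (nm %in% names(centering)) centering[[nm]] else 0,
                numeric(1))
  new("FitResult", family = family, params = pars, coefficients = beta,
      se = seNat, vcov = V, loglik = ll, aic = 2 * k - 2 * ll,
      nBouts = length(t), nEvents = sum(ev),
      centering = if (length(cen)) setNames(cen, covariateNames) else numeric(0),
      dataFingerprint = rlang::hash(list(round(t, 9), ev)),
      convergence = as.integer(best$convergence))
}

#' Rank competing fits by AIC
#'
#' Orders fits of different duration-law families to the same bout set by
#' ascending AIC and reports the AIC difference (delta) to the best model.
#' Ties are broken by fewer parameters, then by a fixed family order
#' (exponential, Weibull, lognormal, power law). Fits on different bout
#' sets are refused.
#'
#' @param fits list of [FitResult-class] objects on identical bout records.
#' @return list with `ranking` (data.frame: `family`, `k`, `loglik`, `aic`,
#'   `delta`) and `fits` (the input fits, ranked).
#' @export
selectModel <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, is, TRUE, "FitResult")))
  fps <- vapply(fits, function(f) f@dataFingerprint, character(1))
  if (length(unique(fps)) != 1L)
    stop("fits were not computed on identical bout sets")
  fam <- vapply(fits, lawFamily, character(1))
  k <- vapply(fits, function(f) length(f@params) + length(f@coefficients), numeric(1))
  aics <- vapply(fits, aic, numeric(1))
  ord <- order(aics, k, match(fam, familyOrder()))
  ranking <- data.frame(
    family = fam[ord], k = as.integer(k[ord]),
    loglik = vapply(fits, logLik, numeric(1))[ord],
    aic = aics[ord], delta = aics[ord] - min(aics),
    stringsAsFactors = FALSE)
  list(ranking = ranking, fits = fits[ord])
}

#' Classify the tail of the selected duration law
#'
#' Maps the AIC-selected family to a tail class: lognormal and power law
#' are heavy-tailed, the exponential is the random-exit reference, and a
#' Weibull with shape > 1 is light-tailed (shape exactly 1 being the
#' exponential boundary). A Weibull winner with shape < 1 is outside that
#' taxonomy — it is labelled heavy with a warning.
#'
#' @param best the AIC-selected [FitResult-class].
#' @return one of `"light"`, `"exponential-like"`, `"heavy"`.
#' @export
classifyTail <- function(best) {
  stopifnot(is(best, "FitResult"))
  switch(best@family,
    lognormal = "heavy",
    powerlaw = "heavy",
    exponential = "exponential-like",
    weibull = {
      shape <- best@params[["shape"]]
      if (shape > 1) "light"
      else if (shape == 1) "exponential-like"
      else {
        warning("Weibull winner with shape < 1: heavy by skew, outside the light/exponential taxonomy")
        "heavy"
      }
    }
  )
}

#' Acceleration factor for one covariate
#'
#' The fitted duration ratio per unit of a covariate, `exp(coefficient)`,
#' with a Wald 95% confidence interval `exp(coef +/- 1.96 se)`.
#'
#' @param fit a [FitResult-class].
#' @param covariate covariate name present in the fit.
#' @param level confidence level.
#' @return named numeric: `factor`, `lower`, `upper`, `coef`, `se`.
#' @export
accelerationFactor <- function(fit, covariate, level = 0.95) {
  stopifnot(is(fit, "FitResult"))
  if (!covariate %in% names(fit@coefficients))
    stop("covariate not in fit: ", covariate)
  b <- fit@coefficients[[covariate]]
  s <- fit@se[[covariate]]
  z <- qnorm(1 - (1 - level) / 2)
  c(factor = exp(b), lower = exp(b - z * s), upper = exp(b + z * s),
    coef = b, se = s)
}

#' Likelihood-ratio test between nested fits
#'
#' Companion to AIC comparison: twice the log-likelihood gain of the full
#' model over the nested one, referred to a chi-square with degrees of
#' freedom equal to the parameter-count difference. Valid nestings are the
#' same family with a subset of covariates, or an exponential inside a
#' Weibull with identical covariates (for which the usual boundary caveat
#' on the chi-square reference applies).
#'
#' @param nested,full [FitResult-class] objects on the same bout records.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
likelihoodRatioTest <- function(nested, full) {
  stopifnot(is(nested, "FitResult"), is(full, "FitResult"))
  if (nested@dataFingerprint != full@dataFingerprint)
    stop("fits are not on the same bout records")
  sameCov <- identical(sort(names(nested@coefficients)), sort(names(full@coefficients)))
  nestedOK <-
    (nested@family == full@family &&
       all(names(nested@coefficients) %in% names(full@coefficients))) ||
    (nested@family == "exponential" && full@family == "weibull" && sameCov)
  if (!nestedOK) stop("models are not nested")
  kN <- length(nested@params) + length(nested@coefficients)
  kF <- length(full@params) + length(full@coefficients)
  df <- kF - kN
  stat <- max(0, 2 * (full@loglik - nested@loglik))
  p <- if (stat < 1e-12) 1 else pchisq(stat, df = max(df, 1), lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}
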