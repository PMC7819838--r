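## Accessors and show methods.

#' @rdname accessors
#' @export
setMethod("states", "Hypnogram", function(object) object@states)

#' @rdname accessors
#' @export
setMethod("events", "Hypnogram", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("covariates", "Hypnogram", function(object) object@covariates)

#' @rdname accessors
#' @export
setMethod("subjectId", "Hypnogram", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("epochLength", "Hypnogram", function(object) object@epochLength)

#' Recording length in minutes
#' @param h a [Hypnogram-class].
#' @return total scored time in minutes.
#' @export
recordingMinutes <- function(h) length(h@states) * h@epochLength / 60

setMethod("show", "Hypnogram", function(object) {
  cat(sprintf("Hypnogram of subject '%s': %d epochs of %gs (%.1f min)\n",
              object@subjectId, length(object@states), object@epochLength,
              recordingMinutes(object)))
  pc <- statePercentages(object)
  cat("  occupancy:", paste(sprintf("%s %.0f%%", names(pc), 100 * pc), collapse = ", "), "\n")
  if (nrow(object@events))
    cat(sprintf("  %d sensory event(s): %s\n", nrow(object@events),
                paste(unique(object@events$kind), collapse = ", ")))
  cv <- object@covariates
  cat(sprintf("  PMA %s wk, cortisol %s ug/dL\n",
              format(cv$pma_weeks), format(cv$cortisol_ug_dl)))
})

#' @rdname accessors
#' @export
setMethod("bouts", "BoutSet", function(object) object@bouts)

#' @rdname accessors
#' @export
setMethod("leftCensored", "BoutSet", function(object) object@leftCensored)

setMethod("show", "BoutSet", function(object) {
  b <- object@bouts
  cat(sprintf("BoutSet: %d modelled bouts (%d offsets observed), %d left-censored run(s)\n",
              nrow(b), sum(b$event_observed), nrow(object@leftCensored)))
  if (nrow(b)) {
    tab <- table(factor(b$state, levels = modelledStates()))
    cat("  by state:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("lawFamily", "FitResult", function(object) object@family)

#' @rdname accessors
#' @export
setMethod("params", "FitResult", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("coefs", "FitResult", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("stdErrors", "FitResult", function(object) object@se)

#' @rdname accessors
#' @export
setMethod("aic", "FitResult", function(object) object@aic)

#' @rdname accessors
#' @export
setMethod("nEvents", "FitResult", function(object) object@nEvents)

#' @export
#' @describeIn FitResult maximised censored log-likelihood.
#' @param object a `FitResult`.
setMethod("logLik", "FitResult", function(object) object@loglik)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s law, %d bouts (%d events), logLik %.3f, AIC %.3f\n",
              object@family, object@nBouts, object@nEvents,
              object@loglik, object@aic))
  p <- object@params
  cat("  baseline:", paste(sprintf("%s %.4g (SE %.3g)", names(p), p,
                                   object@se[names(p)]), collapse = ", "), "\n")
  if (length(object@coefficients)) {
    cf <- object@coefficients
    cat("  AFT factors:", paste(sprintf("%s exp(b)=%.4g", names(cf), exp(cf)),
                                collapse = ", "), "\n")
  }
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve (%s): %d points, t in [%g, %g] min\n",
              object@kind, length(object@time),
              min(object@time), max(object@time)))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (semi-Markov hypnogram generator)\n")
  for (s in modelledStates()) {
    law <- object@durationLaws[[s]]
    cat(sprintf("  %s: %s(%s), PMA factor/wk %.3f\n", s, law$family,
                paste(sprintf("%.4g", law$params), collapse = ", "),
                object@pmaFactors[[s]]))
  }
  cat(sprintf("  cortisol factor (W) %.3f, AS->QS destination factor %.3f\n",
              object@cortisolFactorW, object@nextstateFactorAS))
  cat(sprintf("  recording U(%g, %g) min; lance prob %.2f, trigger prob %.2f (PMA >= %g wk)\n",
              object@recordingRange[1], object@recordingRange[2],
              object@lanceSchedule$prob_lance, object@awakeningTrigger$prob,
              object@awakeningTrigger$pma_min_weeks))
})

#' Convert a SurvivalCurve to a data.frame
#' @param x a [SurvivalCurve-class].
#' @param ... ignored.
#' @return data.frame with columns `time`, `surv`, `lower`, `upper`, `kind`.
#' @export
setMethod("as.data.frame", "SurvivalCurve", function(x, ...) {
  data.frame(time = x@time, surv = x@surv, lower = x@lower,
             upper = x@upper, kind = x@kind)
})
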