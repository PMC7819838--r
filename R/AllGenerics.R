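#' @import methods
#' @importFrom stats dlnorm plnorm qlnorm dweibull pweibull dexp pexp
#'   rlnorm rweibull rexp runif rbinom rgamma optim pchisq pnorm qnorm
#'   sd setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

#' Accessors for neosleep classes
#'
#' Small generic accessor family used across the package's S4 classes.
#' `states()` returns the epoch-by-epoch state labels of a [Hypnogram-class],
#' `events()` its sensory-event table, `covariates()` its subject covariate
#' list. `bouts()` and `leftCensored()` return the modelled and the
#' left-censored bout records of a [BoutSet-class]. `family()` (masked name
#' avoided: `lawFamily()`), `params()`, `coefs()`, `stdErrors()` and
#' `aic()` interrogate a [FitResult-class].
#'
#' @param object an object of the documented class.
#' @return The slot contents, see the class documentation.
#' @name accessors
#' @aliases states events covariates subjectId epochLength bouts leftCensored
#'   lawFamily params coefs stdErrors aic nEvents
NULL

#' @rdname accessors
#' @export
setGeneric("states", function(object) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("epochLength", function(object) standardGeneric("epochLength"))

#' @rdname accessors
#' @export
setGeneric("bouts", function(object) standardGeneric("bouts"))

#' @rdname accessors
#' @export
setGeneric("leftCensored", function(object) standardGeneric("leftCensored"))

#' @rdname accessors
#' @export
setGeneric("lawFamily", function(object) standardGeneric("lawFamily"))

#' @rdname accessors
#' @export
setGeneric("params", function(object) standardGeneric("params"))

#' @rdname accessors
#' @export
setGeneric("coefs", function(object) standardGeneric("coefs"))

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))

#' @rdname accessors
#' @export
setGeneric("aic", function(object) standardGeneric("aic"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
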