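## Semi-Markov (alternating-renewal) hypnogram generator. States alternate
## according to an embedded transition chain while sojourn durations follow
## arbitrary state-specific laws; covariates act multiplicatively on
## durations (AFT-consistent). For active sleep the offset destination is
## drawn *before* the duration, so the destination-dependent duration law
## is a generative mechanism, not just a fitted association.

#' Analytic state occupancy of a simulator configuration
#'
#' Renewal-reward occupancy over the modelled states: the stationary
#' distribution of the embedded transition chain weighted by mean state
#' durations (with the covariate multipliers and the active-sleep
#' destination mixture applied), normalised to 1. Transitional-sleep
#' filler is excluded.
#'
#' @param config a [SimConfig-class].
#' @param covariates named list with `pma_weeks` and optionally
#'   `cortisol_ug_dl` (missing values fall back to the reference).
#' @return named fractions over `W`, `AS`, `QS` summing to 1.
#' @export
expectedOccupancy <- function(config, covariates = list()) {
  stopifnot(is(config, "SimConfig"))
  st <- modelledStates()
  P <- config@transitionProbs
  ## recurrent communicating class of the embedded chain; transient states
  ## (never revisited) get zero stationary weight, and a chain with more
  ## than one closed class has no unique stationary distribution
  M <- diag(3) + (P > 0)
  reach <- (M %*% M %*% M) > 0
  recurrent <- vapply(1:3, function(i) all(!reach[i, ] | reach[, i]), logical(1))
  if (!any(recurrent)) stop("reducible transition chain")
  R <- which(recurrent)
  if (!all(reach[R[1], R] & reach[R, R[1]]))
    stop("reducible transition chain: no unique stationary distribution")
  pi_embed <- setNames(numeric(3), st)
  nR <- length(R)
  A <- rbind(t(P[R, R, drop = FALSE]) - diag(nR), rep(1, nR))
  pi_embed[R] <- drop(qr.solve(A, c(rep(0, nR), 1)))

  means <- vapply(st, function(s) {
    law <- config@durationLaws[[s]]
    m <- familyMean(law$family, law$params) * durationMultiplier(config, s, covariates)
    if (s == "AS") {
      pQS <- P["AS", "QS"]
      m <- m * (pQS * config@nextstateFactorAS + (1 - pQS))
    }
    m
  }, numeric(1))
  occ <- pi_embed * means
  occ / sum(occ)
}

## covariate multiplier on durations for state s (destination effect applied
## separately at draw time)
durationMultiplier <- function(config, s, covariates) {
  pma <- covariates$pma_weeks
  m <- if (is.null(pma) || is.na(pma)) 1
       else config@pmaFactors[[s]]^(pma - config@pmaCenter)
  if (s == "W") {
    cort <- covariates$cortisol_ug_dl
    if (!is.null(cort) && !is.na(cort))
      m <- m * config@cortisolFactorW^((cort - config@cortisolCenter) * 10)
  }
  m
}

#' Simulate one subject's hypnogram
#'
#' Alternating-renewal construction: the initial state is drawn from the
#' analytic occupancy and its duration from the equilibrium residual-life
#' distribution (so the process is time-stationary; the extractor discards
#' this first, left-censored run). Each subsequent bout draws its offset
#' destination from the transition chain, then its duration from the
#' state's law with the covariate (and, for active sleep, destination)
#' multipliers, quantised to epochs with a two-epoch floor.
#' Transitional-sleep filler is inserted at state changes with the
#' configured probability. The sequence is truncated at the drawn
#' recording length. A scheduled heel lance falling inside an active-sleep
#' bout truncates it into an awakening with the configured probability,
#' only for subjects at or above the gating postmenstrual age.
#'
#' @param config a [SimConfig-class].
#' @param covariates named list of subject covariates (needs `pma_weeks`).
#' @param seed integer seed; identical seed, config and covariates give an
#'   identical hypnogram.
#' @param subjectId identifier for the generated recording.
#' @return a [Hypnogram-class].
#' @export
simulateSubject <- function(config, covariates, seed = NULL, subjectId = "sim1") {
  stopifnot(is(config, "SimConfig"))
  if (is.null(covariates$pma_weeks) || is.na(covariates$pma_weeks))
    stop("covariates must include pma_weeks")
  if (!is.null(seed)) set.seed(seed)
  epMin <- config@epochLength / 60
  st <- modelledStates()
  P <- config@transitionProbs

  L <- runif(1, config@recordingRange[1], config@recordingRange[2])
  nEpochs <- max(4L, floor(L / epMin))
  totalMin <- nEpochs * epMin

  ## sensory event schedule
  evt <- data.frame(time_min = numeric(0), kind = character(0))
  if (runif(1) < config@lanceSchedule$prob_lance)
    evt <- rbind(evt, data.frame(time_min = runif(1, 0, totalMin), kind = "lance"))
  if (runif(1) < config@lanceSchedule$prob_non_noxious)
    evt <- rbind(evt, data.frame(time_min = runif(1, 0, totalMin), kind = "non_noxious"))
  lancePending <- evt$time_min[evt$kind == "lance"]
  gateOpen <- covariates$pma_weeks >= config@awakeningTrigger$pma_min_weeks

  drawDest <- function(s) sample(st, 1, prob = P[s, ])
  drawDur <- function(s, dest, residual = FALSE) {
    law <- config@durationLaws[[s]]
    d <- if (residual) familyDrawResidual(law$family, law$params, 1)
         else familyDraw(law$family, law$params, 1)
    m <- durationMultiplier(config, s, covariates)
    if (s == "AS" && identical(dest, "QS")) m <- m * config@nextstateFactorAS
    d * m
  }

  occ <- expectedOccupancy(config, covariates)
  state <- sample(st, 1, prob = occ)
  ## length-biased destination for the stationary first active-sleep run
  dest <- if (state == "AS") {
    pQS <- P["AS", "QS"] * config@nextstateFactorAS
    pW <- P["AS", "W"]
    sample(c("QS", "W"), 1, prob = c(pQS, pW))
  } else drawDest(state)
  first <- TRUE

  statesOut <- character(0)
  remaining <- nEpochs
  while (remaining > 0L) {
    dur <- drawDur(state, dest, residual = first)
    nE <- max(2L, as.integer(round(dur / epMin)))
    runStart <- (nEpochs - remaining) * epMin
    triggered <- FALSE
    if (state == "AS" && gateOpen && length(lancePending)) {
      runEnd <- runStart + min(nE, remaining) * epMin
      hit <- which(lancePending >= runStart & lancePending < runEnd)
      if (length(hit) && runif(1) < config@awakeningTrigger$prob) {
        tl <- lancePending[hit[1]]
        lancePending <- lancePending[-hit[1]]
        ## awakening latency: truncated-exponential, < 5 min after the lance
        r <- config@awakeningTrigger$latency_rate
        lat <- stats::qexp(runif(1) * stats::pexp(5, r), r)
        nTrunc <- as.integer(ceiling((tl + lat - runStart) / epMin))
        nTrunc <- max(2L, nTrunc)
        if (nTrunc < nE) { nE <- nTrunc; dest <- "W"; triggered <- TRUE }
      }
    }
    nE <- min(nE, remaining)
    statesOut <- c(statesOut, rep(state, nE))
    remaining <- remaining - nE
    first <- FALSE
    if (remaining <= 0L) break
    ## transitional-sleep filler at the state change (not after an abrupt
    ## lance-evoked awakening)
    if (!triggered && runif(1) < config@tsInsertion$prob) {
      tsDur <- rlnorm(1, config@tsInsertion$meanlog, config@tsInsertion$sdlog)
      nTS <- min(max(2L, as.integer(round(tsDur / epMin))), remaining)
      statesOut <- c(statesOut, rep("TS", nTS))
      remaining <- remaining - nTS
      if (remaining <= 0L) break
    }
    state <- dest
    dest <- drawDest(state)
  }

  Hypnogram(subjectId, statesOut, epochLength = config@epochLength,
            events = if (nrow(evt)) evt else NULL, covariates = covariates)
}

#' Default cohort covariate sampler
#'
#' Postmenstrual age uniform on 28-40 weeks, postnatal age uniform on 1-60
#' days, a 30% high-risk fraction, and salivary cortisol lognormal
#' (median 0.3, log-sd 0.45 micrograms/dL, spanning roughly 0.11-0.81).
#'
#' @param n number of subjects.
#' @return data.frame of per-subject covariates.
#' @export
defaultCovariateSampler <- function(n) {
  data.frame(
    pma_weeks = runif(n, 28, 40),
    postnatal_age_days = round(runif(n, 1, 60)),
    risk_high = rbinom(n, 1, 0.3),
    cortisol_ug_dl = rlnorm(n, meanlog = log(0.3), sdlog = 0.45))
}

#' Simulate a cohort of hypnograms
#'
#' Per-subject covariates come from `covariateSampler`; each subject then
#' gets an independent stream seeded deterministically from the master
#' seed, so the whole cohort is reproducible bit-for-bit.
#'
#' @param config a [SimConfig-class].
#' @param nSubjects number of subjects (>= 1).
#' @param seed master integer seed.
#' @param covariateSampler `function(n)` returning a covariate data.frame.
#' @return list with elements `hypnograms` (list of [Hypnogram-class]),
#'   `covariates` (data.frame), `truth` (the [SimConfig-class]) and `seed`.
#' @export
#' @examples
#' coh <- simulateCohort(simConfig(), 3, seed = 1)
#' length(coh$hypnograms)
simulateCohort <- function(config, nSubjects, seed = 1,
                           covariateSampler = defaultCovariateSampler) {
  stopifnot(nSubjects >= 1)
  set.seed(seed)
  covs <- covariateSampler(nSubjects)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
  hyps <- lapply(seq_len(nSubjects), function(i)
    simulateSubject(config, as.list(covs[i, , drop = FALSE]),
                    seed = subSeeds[i],
                    subjectId = sprintf("sim%04d", i)))
  list(hypnograms = hyps, covariates = covs, truth = config, seed = seed)
}

#' Simulate bout durations with subject covariate effects
#'
#' Bout-level generator with the accelerated-failure-time covariate
#' structure: each row of `covariates` contributes one bout whose duration
#' is drawn from the configured law for `state`, multiplied by the
#' per-week postmenstrual-age factor (and, for wake, the cortisol factor;
#' for active sleep with `destinationEffect`, the destination factor with
#' the destination drawn first). Durations are optionally right-censored
#' at an independent uniform recording length.
#'
#' @param config a [SimConfig-class].
#' @param state one of `W`, `AS`, `QS`.
#' @param covariates data.frame with `pma_weeks` and optionally
#'   `cortisol_ug_dl` (one bout per row).
#' @param destinationEffect active sleep only: draw the offset destination
#'   first and apply the destination duration multiplier.
#' @param censor `"recording"` or `"none"` as in [simulateBoutDurations()].
#' @return data.frame with `duration_min`, `event_observed`, the covariate
#'   columns, and destination columns when requested.
#' @export
simulateCovariateBouts <- function(config, state, covariates,
                                   destinationEffect = FALSE,
                                   censor = c("recording", "none")) {
  stopifnot(is(config, "SimConfig"), state %in% modelledStates(),
            "pma_weeks" %in% names(covariates))
  censor <- match.arg(censor)
  n <- nrow(covariates)
  law <- config@durationLaws[[state]]
  mult <- config@pmaFactors[[state]]^(covariates$pma_weeks - config@pmaCenter)
  if (state == "W" && "cortisol_ug_dl" %in% names(covariates)) {
    cort <- covariates$cortisol_ug_dl
    ok <- !is.na(cort)
    mult[ok] <- mult[ok] *
      config@cortisolFactorW^((cort[ok] - config@cortisolCenter) * 10)
  }
  out <- data.frame(duration_min = familyDraw(law$family, law$params, n) * mult,
                    event_observed = 1L)
  out$pma_weeks <- covariates$pma_weeks
  if ("cortisol_ug_dl" %in% names(covariates))
    out$cortisol_ug_dl <- covariates$cortisol_ug_dl
  if (destinationEffect) {
    if (state != "AS") stop("destination effect applies to active sleep only")
    P <- config@transitionProbs
    dest <- sample(c("QS", "W"), n, replace = TRUE,
                   prob = c(P["AS", "QS"], P["AS", "W"]))
    qs <- dest == "QS"
    out$duration_min[qs] <- out$duration_min[qs] * config@nextstateFactorAS
    out$next_state <- dest
    out$dest_qs <- as.numeric(qs)
  }
  if (censor == "recording") {
    C <- runif(n, config@recordingRange[1], config@recordingRange[2])
    cens <- out$duration_min > C
    out$event_observed[cens] <- 0L
    out$duration_min[cens] <- C[cens]
    if (destinationEffect) out$next_state[cens] <- NA_character_
  }
  out
}

#' Simulate raw bout durations from one state's law
#'
#' Bout-level generator used for estimator validation: durations are drawn
#' straight from the configured law for `state` at the covariate reference
#' (no epoch quantisation), optionally with the active-sleep destination
#' mechanism, and right-censored at an independent uniform recording
#' length drawn from the config's `recordingRange`.
#'
#' @param config a [SimConfig-class].
#' @param state one of `W`, `AS`, `QS`.
#' @param n number of bouts.
#' @param destinationEffect draw the offset destination first (active sleep
#'   only) and apply the destination duration multiplier; adds `next_state`
#'   and `dest_qs` columns.
#' @param censor `"recording"` to right-censor each bout at an independent
#'   uniform draw from `recordingRange`, `"none"` for fully observed bouts.
#' @return data.frame with columns `duration_min`, `event_observed` (and
#'   destination columns when requested).
#' @export
simulateBoutDurations <- function(config, state, n,
                                  destinationEffect = FALSE,
                                  censor = c("recording", "none")) {
  stopifnot(is(config, "SimConfig"), state %in% modelledStates())
  censor <- match.arg(censor)
  law <- config@durationLaws[[state]]
  t <- familyDraw(law$family, law$params, n)
  out <- data.frame(duration_min = t, event_observed = 1L)
  if (destinationEffect) {
    if (state != "AS") stop("destination effect applies to active sleep only")
    P <- config@transitionProbs
    dest <- sample(c("QS", "W"), n, replace = TRUE,
                   prob = c(P["AS", "QS"], P["AS", "W"]))
    qs <- dest == "QS"
    out$duration_min[qs] <- out$duration_min[qs] * config@nextstateFactorAS
    out$next_state <- dest
    out$dest_qs <- as.numeric(qs)
  }
  if (censor == "recording") {
    C <- runif(n, config@recordingRange[1], config@recordingRange[2])
    cens <- out$duration_min > C
    out$event_observed[cens] <- 0L
    out$duration_min[cens] <- C[cens]
    if (destinationEffect) out$next_state[cens] <- NA_character_
  }
  out
}
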