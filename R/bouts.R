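## Bout extraction: hypnogram epochs -> censored survival records.
##
## Conventions: epochs are 0-based; a bout's onset is the start time of the
## first epoch of its run; durations are run length x epochLength. A state
## change is only scored when the new state persists for at least
## `minEpochs` epochs (1 minute at 30-s epochs).

#' Enforce the minimum state-change rule
#'
#' Scoring requires the new sleep-wake state to persist for at least one
#' minute (two 30-s epochs). Any maximal run shorter than `minEpochs` that
#' is not at the start or end of the recording is relabelled to the state of
#' the preceding run: when both flanking runs share a state this merges the
#' interruption into it, and when they differ the ongoing bout is
#' conservatively continued so the eventual transition is scored at the
#' start of the next full-length run. The operation is idempotent. Runs at
#' the recording edges are left untouched (they are censoring matters, not
#' scoring matters).
#'
#' @param x a [Hypnogram-class] or a character vector of epoch states.
#' @param minEpochs minimum run length, in epochs, for a scored state change.
#' @return an object of the same type as `x` with relabelled states.
#' @export
#' @examples
#' enforceMinStateRule(c(rep("AS", 4), "QS", rep("AS", 4)))
enforceMinStateRule <- function(x, minEpochs = 2) {
  if (is(x, "Hypnogram")) {
    x@states <- enforceMinStateRule(x@states, minEpochs)
    return(x)
  }
  stopifnot(length(x) > 0)
  states <- x
  repeat {
    r <- rle(states)
    nr <- length(r$lengths)
    if (nr < 2) break
    short <- which(r$lengths < minEpochs)
    if (!length(short)) break
    i <- short[1]
    ## a leading sub-minimum run joins the following state (it cannot be a
    ## scored state of its own); anything else joins the preceding state
    r$values[i] <- if (i == 1L) r$values[2] else r$values[i - 1]
    states <- inverse.rle(r)
  }
  states
}

#' Extract censored bout records from a hypnogram
#'
#' Converts the epoch sequence into the survival-analysis substrate: one
#' record per maximal run of a modelled state (`W`, `AS`, `QS`). The first
#' run of the recording has no observed onset and is returned separately as
#' left-censored (it is excluded from duration modelling). A run reaching
#' the end of the recording is right-censored (`event_observed = 0`).
#' Transitional sleep (`TS`) never forms a bout: a TS run of at least
#' `minEpochs` terminates the preceding bout and the recorded `next_state`
#' is the first non-TS state after it (`NA` if the recording ends in TS); a
#' shorter trailing TS run leaves the preceding bout censored.
#'
#' @param h a [Hypnogram-class].
#' @param minEpochs minimum scoreable run length in epochs.
#' @param applyMinRule apply [enforceMinStateRule()] first (idempotent, so
#'   harmless when the states were already cleaned).
#' @return a [BoutSet-class].
#' @export
#' @examples
#' h <- Hypnogram("s1", c(rep("W", 4), rep("AS", 10), rep("QS", 6)))
#' bouts(extractBouts(h))
extractBouts <- function(h, minEpochs = 2, applyMinRule = TRUE) {
  stopifnot(is(h, "Hypnogram"))
  st <- if (applyMinRule) enforceMinStateRule(h@states, minEpochs) else h@states
  epmin <- h@epochLength / 60
  r <- rle(st)
  nr <- length(r$lengths)
  run_start <- c(0L, cumsum(r$lengths))[seq_len(nr)]

  cv <- h@covariates
  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    s <- r$values[i]
    if (s == "TS") next
    ## look through TS for the offset destination
    ev <- 0L; nxt <- NA_character_
    if (i < nr) {
      j <- i + 1L
      if (r$values[j] != "TS") {
        ev <- 1L; nxt <- r$values[j]
      } else if (r$lengths[j] >= minEpochs) {
        ## a full-length TS run terminates the bout
        ev <- 1L
        k <- j + 1L
        while (k <= nr && r$values[k] == "TS") k <- k + 1L
        if (k <= nr) nxt <- r$values[k]
      }                                  # short trailing TS: bout censored
    }
    rows[[i]] <- data.frame(
      subject_id = h@subjectId, state = s,
      onset_min = run_start[i] * epmin,
      duration_min = r$lengths[i] * epmin,
      onset_captured = as.integer(i > 1L),
      event_observed = ev, next_state = nxt,
      pma_weeks = cv$pma_weeks %||% NA_real_,
      postnatal_age_days = cv$postnatal_age_days %||% NA_real_,
      risk_high = cv$risk_high %||% NA_real_,
      cortisol_ug_dl = cv$cortisol_ug_dl %||% NA_real_,
      stringsAsFactors = FALSE
    )
  }
  all_runs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(all_runs)) all_runs <- emptyBoutFrame()
  new("BoutSet",
      bouts = all_runs[all_runs$onset_captured == 1L, , drop = FALSE],
      leftCensored = all_runs[all_runs$onset_captured == 0L, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyBoutFrame <- function() {
  data.frame(subject_id = character(0), state = character(0),
             onset_min = numeric(0), duration_min = numeric(0),
             onset_captured = integer(0), event_observed = integer(0),
             next_state = character(0), pma_weeks = numeric(0),
             postnatal_age_days = numeric(0), risk_high = numeric(0),
             cortisol_ug_dl = numeric(0), stringsAsFactors = FALSE)
}

#' Extract bouts from a list of hypnograms
#'
#' @param cohort list of [Hypnogram-class] objects.
#' @param ... passed to [extractBouts()].
#' @return a [BoutSet-class] with all subjects' records stacked.
#' @export
extractCohortBouts <- function(cohort, ...) {
  sets <- lapply(cohort, extractBouts, ...)
  new("BoutSet",
      bouts = do.call(rbind, c(lapply(sets, bouts), list(emptyBoutFrame()))),
      leftCensored = do.call(rbind, c(lapply(sets, leftCensored),
                                      list(emptyBoutFrame()))))
}

#' Fraction of recording time spent in each state
#'
#' Epoch-count occupancy per state, in the order `W`, `AS`, `TS`, `QS`.
#'
#' @param h a [Hypnogram-class].
#' @return named numeric vector of fractions summing to 1.
#' @export
statePercentages <- function(h) {
  stopifnot(is(h, "Hypnogram"))
  if (!length(h@states)) stop("empty hypnogram")
  tab <- table(factor(h@states, levels = sleepStates()))
  setNames(as.numeric(tab) / length(h@states), sleepStates())
}

#' Transition bookkeeping for a bout set
#'
#' For each modelled state, counts of observed offsets into each destination
#' state, offsets into an unknown destination (recording ended in
#' transitional sleep) and right-censored bouts. Row sums equal the number
#' of modelled bouts per state.
#'
#' @param x a [BoutSet-class] or its `bouts()` data.frame.
#' @return integer matrix with rows `W`, `AS`, `QS` and columns `W`, `AS`,
#'   `QS`, `unknown`, `censored`.
#' @export
transitionTable <- function(x) {
  b <- if (is(x, "BoutSet")) bouts(x) else x
  st <- modelledStates()
  out <- matrix(0L, 3, 5, dimnames = list(st, c(st, "unknown", "censored")))
  if (!nrow(b)) return(out)
  for (s in st) {
    bs <- b[b$state == s, , drop = FALSE]
    out[s, "censored"] <- sum(bs$event_observed == 0L)
    out[s, "unknown"] <- sum(bs$event_observed == 1L & is.na(bs$next_state))
    obs <- bs$next_state[bs$event_observed == 1L & !is.na(bs$next_state)]
    tab <- table(factor(obs, levels = st))
    out[s, st] <- as.integer(tab)
  }
  out
}
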