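## Sensory-perturbation window analysis: do awakenings cluster in the
## minutes after a noxious heel lance, relative to sleep-to-sleep
## transitions and to non-noxious control stimuli?

#' State-transition events of a bout set
#'
#' One row per observed bout offset: the transition time (bout onset +
#' duration), origin and destination state, and its class — `awakening`
#' when the destination is wakefulness, `sleep_to_sleep` otherwise.
#' Censored bouts and offsets with unknown destination contribute nothing.
#'
#' @param x a [BoutSet-class] or its `bouts()` data.frame.
#' @return data.frame with columns `subject_id`, `time_min`, `from_state`,
#'   `to_state`, `transition_class`, `pma_weeks`.
#' @export
transitionEvents <- function(x) {
  b <- if (is(x, "BoutSet")) bouts(x) else x
  b <- b[b$event_observed == 1 & !is.na(b$next_state), , drop = FALSE]
  data.frame(
    subject_id = b$subject_id,
    time_min = b$onset_min + b$duration_min,
    from_state = b$state, to_state = b$next_state,
    transition_class = ifelse(b$next_state == "W", "awakening", "sleep_to_sleep"),
    pma_weeks = if ("pma_weeks" %in% names(b)) b$pma_weeks else NA_real_,
    stringsAsFactors = FALSE)
}

#' Gather sensory events of a cohort
#'
#' @param cohort list of [Hypnogram-class] objects.
#' @return data.frame with columns `subject_id`, `time_min`, `kind`.
#' @export
sensoryEvents <- function(cohort) {
  rows <- lapply(cohort, function(h) {
    ev <- events(h)
    if (!nrow(ev)) return(NULL)
    data.frame(subject_id = subjectId(h), time_min = ev$time_min,
               kind = ev$kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), time_min = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  out
}

#' Cross-classify transitions by event window
#'
#' Counts transitions of each class falling within versus outside the
#' `[0, windowMin)`-minute window after any event of the chosen kind (same
#' subject); a transition inside overlapping windows is counted once.
#'
#' @param transitions data.frame per [transitionEvents()].
#' @param events data.frame per [sensoryEvents()].
#' @param kind event kind defining the windows (`"lance"` or
#'   `"non_noxious"`).
#' @param windowMin window length in minutes.
#' @return 2x2 integer matrix, rows `awakening`/`sleep_to_sleep`, columns
#'   `within`/`outside`.
#' @export
windowCounts <- function(transitions, events, kind = "lance", windowMin = 5) {
  stopifnot(windowMin > 0)
  ev <- events[events$kind == kind, , drop = FALSE]
  within <- vapply(seq_len(nrow(transitions)), function(i) {
    e <- ev[ev$subject_id == transitions$subject_id[i], , drop = FALSE]
    if (!nrow(e)) return(FALSE)
    dt <- transitions$time_min[i] - e$time_min
    any(dt >= 0 & dt < windowMin)
  }, logical(1))
  cls <- factor(transitions$transition_class,
                levels = c("awakening", "sleep_to_sleep"))
  out <- table(cls, factor(ifelse(within, "within", "outside"),
                           levels = c("within", "outside")))
  m <- matrix(as.integer(out), 2, 2,
              dimnames = list(c("awakening", "sleep_to_sleep"),
                              c("within", "outside")))
  m
}

#' Likelihood-ratio (G) test of association with Cramer's V
#'
#' G-statistic for independence in a contingency table
#' (`2 * sum(obs * log(obs / expected))`, with `0 log 0 = 0`), chi-square
#' reference, and the Cramer's V effect size `sqrt(G / (n * min(r-1, c-1)))`.
#'
#' @param tab contingency table (matrix of non-negative counts).
#' @return list with `G`, `df`, `p.value`, `cramers_v`, `n`.
#' @export
#' @examples
#' associationTest(matrix(c(10, 10, 10, 10), 2))  # independence: G = 0
associationTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rs, cs) / n
  terms <- ifelse(tab > 0, tab * log(tab / expected), 0)
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  V <- sqrt(G / (n * min(nrow(tab) - 1, ncol(tab) - 1)))
  list(G = G, df = df, p.value = pchisq(G, df, lower.tail = FALSE),
       cramers_v = min(V, 1), n = n)
}

#' Latencies from the most recent prior event
#'
#' For each transition, the time since the latest event of the given kind
#' at or before it (same subject); transitions with no prior event are
#' excluded.
#'
#' @inheritParams windowCounts
#' @return numeric vector of latencies in minutes.
#' @export
latenciesToTransition <- function(transitions, events, kind = "lance") {
  ev <- events[events$kind == kind, , drop = FALSE]
  if (!nrow(ev)) stop("no events of kind: ", kind)
  lat <- vapply(seq_len(nrow(transitions)), function(i) {
    e <- ev[ev$subject_id == transitions$subject_id[i] &
              ev$time_min <= transitions$time_min[i], , drop = FALSE]
    if (!nrow(e)) return(NA_real_)
    transitions$time_min[i] - max(e$time_min)
  }, numeric(1))
  lat[!is.na(lat)]
}

#' Adjusted Fisher-Pearson skewness
#'
#' The small-sample-corrected standardised third moment,
#' `G1 = g1 * sqrt(n (n-1)) / (n - 2)` with
#' `g1 = m3 / m2^(3/2)`, used to summarise the right-skew of latency
#' distributions.
#'
#' @param x numeric vector, at least 3 values with positive variance.
#' @return scalar skewness.
#' @export
#' @examples
#' latencySkewness(c(1, 2, 3))  # symmetric: 0
latencySkewness <- function(x) {
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance: skewness undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
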