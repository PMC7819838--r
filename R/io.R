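## Delimited-text interfaces.
##
## Epoch table (TSV or CSV): subject_id, epoch_index (0-based), state; an
## optional comment line `#epoch_length_s=30` overrides the epoch length.
## Covariate table (CSV): subject_id, gestational_age_weeks,
## postnatal_age_days, pma_weeks, risk_high, cortisol_ug_dl.
## Event table (CSV): subject_id, time_s, event_type.

epochSep <- function(path) if (grepl("\\.tsv$", path)) "\t" else ","

readEpochHeader <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#epoch_length_s=", first))
    as.numeric(sub("^#epoch_length_s=", "", first))
  else 30
}

#' Read an epoch-scored state table
#'
#' @param path epoch table path (`.tsv` tab-separated, otherwise comma).
#' @return named list of per-subject data.frames, plus the epoch length as
#'   attribute `epoch_length_s`.
#' @keywords internal
readEpochTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  epochLen <- readEpochHeader(path)
  df <- utils::read.table(path, sep = epochSep(path), header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "epoch_index", "state")
  if (!all(need %in% names(df)))
    stop("epoch table must have columns ", paste(need, collapse = ", "))
  bad <- which(!df$state %in% sleepStates())
  if (length(bad))
    stop(sprintf("parse error in %s, data row %d: unknown state code '%s'",
                 path, bad[1], df$state[bad[1]]))
  if (anyNA(df$epoch_index) || any(df$epoch_index < 0))
    stop("parse error in ", path, ": bad epoch_index")
  out <- split(df, df$subject_id)
  out <- lapply(out, function(d) d[order(d$epoch_index), , drop = FALSE])
  attr(out, "epoch_length_s") <- epochLen
  out
}

covariateColumns <- function() {
  c("subject_id", "gestational_age_weeks", "postnatal_age_days",
    "pma_weeks", "risk_high", "cortisol_ug_dl")
}

#' @keywords internal
readCovariateTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(covariateColumns(), names(df))
  if (length(missing))
    stop("covariate table missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' @keywords internal
readEventTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_s", "event_type")
  if (!all(need %in% names(df)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  ok <- c("lance", "non_noxious", "held_start", "held_end")
  bad <- which(!df$event_type %in% ok)
  if (length(bad))
    stop(sprintf("parse error in %s, data row %d: unknown event_type '%s'",
                 path, bad[1], df$event_type[bad[1]]))
  df
}

#' Read hypnograms from delimited tables
#'
#' `readCohort()` assembles one [Hypnogram-class] per subject from an epoch
#' table plus optional covariate and event tables. `readHypnogram()` is the
#' single-subject convenience (errors when the file holds several subjects
#' and none is named).
#'
#' @param epochPath epoch table (TSV/CSV; see the format notes in the
#'   package vignette).
#' @param covariatePath,eventPath optional CSV tables.
#' @param subject subject to extract (for `readHypnogram`).
#' @return `readCohort()`: named list of [Hypnogram-class];
#'   `readHypnogram()`: one [Hypnogram-class].
#' @export
readCohort <- function(epochPath, covariatePath = NULL, eventPath = NULL) {
  tabs <- readEpochTable(epochPath)
  epochLen <- attr(tabs, "epoch_length_s")
  covs <- if (!is.null(covariatePath)) readCovariateTable(covariatePath) else NULL
  evs <- if (!is.null(eventPath)) readEventTable(eventPath) else NULL
  out <- lapply(names(tabs), function(sid) {
    cv <- list()
    if (!is.null(covs)) {
      row <- covs[covs$subject_id == sid, , drop = FALSE]
      if (nrow(row) == 1)
        cv <- list(pma_weeks = row$pma_weeks,
                   postnatal_age_days = row$postnatal_age_days,
                   risk_high = row$risk_high,
                   cortisol_ug_dl = row$cortisol_ug_dl)
    }
    ev <- NULL
    if (!is.null(evs)) {
      e <- evs[evs$subject_id == sid, , drop = FALSE]
      if (nrow(e))
        ev <- data.frame(time_min = e$time_s / 60, kind = e$event_type,
                         stringsAsFactors = FALSE)
    }
    Hypnogram(sid, tabs[[sid]]$state, epochLength = epochLen,
              events = ev, covariates = cv)
  })
  names(out) <- names(tabs)
  out
}

#' @rdname readCohort
#' @export
readHypnogram <- function(epochPath, covariatePath = NULL, eventPath = NULL,
                          subject = NULL) {
  coh <- readCohort(epochPath, covariatePath, eventPath)
  if (!is.null(subject)) {
    if (!subject %in% names(coh)) stop("subject not in file: ", subject)
    return(coh[[subject]])
  }
  if (length(coh) != 1L)
    stop("file holds ", length(coh), " subjects; name one with `subject=`")
  coh[[1]]
}

#' Write a cohort as epoch/covariate/event tables
#'
#' Emits `epochs.tsv` (with an `#epoch_length_s=` header line),
#' `covariates.csv` and `events.csv` under `dir`, in the formats read by
#' [readCohort()].
#'
#' @param hypnograms list of [Hypnogram-class] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeCohort <- function(hypnograms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  epochLen <- epochLength(hypnograms[[1]])

  epochs <- do.call(rbind, lapply(hypnograms, function(h)
    data.frame(subject_id = subjectId(h),
               epoch_index = seq_along(states(h)) - 1L,
               state = states(h), stringsAsFactors = FALSE)))
  epochPath <- file.path(dir, "epochs.tsv")
  con <- file(epochPath, "w")
  writeLines(sprintf("#epoch_length_s=%g", epochLen), con)
  utils::write.table(epochs, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)

  covs <- do.call(rbind, lapply(hypnograms, function(h) {
    cv <- covariates(h)
    data.frame(subject_id = subjectId(h),
               gestational_age_weeks = cv$pma_weeks -
                 ifelse(is.na(cv$postnatal_age_days), 0, cv$postnatal_age_days) / 7,
               postnatal_age_days = cv$postnatal_age_days,
               pma_weeks = cv$pma_weeks, risk_high = cv$risk_high,
               cortisol_ug_dl = cv$cortisol_ug_dl, stringsAsFactors = FALSE)
  }))
  covPath <- file.path(dir, "covariates.csv")
  write.csv(covs, covPath, row.names = FALSE, quote = FALSE)

  evs <- do.call(rbind, lapply(hypnograms, function(h) {
    ev <- events(h)
    if (!nrow(ev)) return(NULL)
    data.frame(subject_id = subjectId(h), time_s = ev$time_min * 60,
               event_type = ev$kind, stringsAsFactors = FALSE)
  }))
  evPath <- file.path(dir, "events.csv")
  if (is.null(evs))
    evs <- data.frame(subject_id = character(0), time_s = numeric(0),
                      event_type = character(0))
  write.csv(evs, evPath, row.names = FALSE, quote = FALSE)

  invisible(c(epochs = epochPath, covariates = covPath, events = evPath))
}

#' Write bout records as CSV
#'
#' One row per bout with censoring encoded in the 0/1 `event_observed`
#' column (1 = offset captured), the survival-analysis convention.
#'
#' @param boutSet a [BoutSet-class].
#' @param path output CSV path.
#' @param which `"modelled"` (default) or `"left_censored"`.
#' @return invisibly, `path`.
#' @export
writeBouts <- function(boutSet, path, which = c("modelled", "left_censored")) {
  which <- match.arg(which)
  df <- if (which == "modelled") bouts(boutSet) else leftCensored(boutSet)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
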