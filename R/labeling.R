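#' Personalized relative cognitive load of a trial
#'
#' Relative load is the trial's span divided by the participant's maximum
#' span attempted; trials strictly above the threshold (default 0.6) are
#' labeled high load. Because each participant's hardest trials sit at load
#' 1, the dichotomization is personalized: the same span can be high load for
#' a weak performer and low load for a strong one.
#'
#' @param span Trial span(s), digits (vectorized).
#' @param max_span_attempted Participant's maximum span attempted.
#' @param threshold High/low boundary on relative load; comparison is strict
#'   (`>`), so a load of exactly 0.6 is low.
#' @return Data frame with `relative_load` and `is_high`.
#' @export
#' @examples
#' compute_load(c(4, 3, 8), c(6, 5, 8))
compute_load <- function(span, max_span_attempted, threshold = 0.6) {
  if (any(span < 2) || any(span > max_span_attempted))
    verr("invalid_parameter",
         "need 2 <= span <= max_span_attempted for every trial")
  if (threshold <= 0 || threshold >= 1)
    verr("invalid_parameter", "threshold must be in (0, 1)")
  load <- span / max_span_attempted
  data.frame(relative_load = load, is_high = load > threshold)
}

#' Filter a cohort to the analysis set and label loads
#'
#' Applies the inclusion rules: participants with no correct (adjudicated)
#' trials are excluded (`no_correct_responses`), participants whose maximum
#' achieved span is below three are excluded (`span_below_three`), incorrect
#' trials of remaining participants are dropped (`incorrect_trial`), and
#' participants left with fewer than two trials are excluded
#' (`insufficient_trials`, since within-subject normalization needs a
#' within-participant SD). Every excluded trial is logged with its reason, so
#' included + excluded rows always reconcile with the cohort total.
#'
#' @param cohort A `vocload_cohort` from [generate_cohort()].
#' @param threshold High/low load boundary passed to [compute_load()].
#' @return A `vocload_analysis`: list with `trials` (included trials with
#'   `relative_load`, `is_high`), `features` (raw, rows matching `trials`),
#'   `features_norm` (`NULL` until [normalize_within_subject()]),
#'   `exclusions` (participant_id, trial_id, reason), and `threshold`.
#' @export
filter_cohort <- function(cohort, threshold = 0.6) {
  tr <- cohort$trials
  if (is.null(tr) || nrow(tr) == 0L) verr("empty_input", "cohort has no trials")
  sess <- cohort$sessions
  correct_by_pid <- tapply(tr$adjudication == "correct", tr$participant_id, any)

  reason_pid <- setNames(rep(NA_character_, nrow(sess)), sess$participant_id)
  reason_pid[names(correct_by_pid)[!correct_by_pid]] <- "no_correct_responses"
  below3 <- sess$participant_id[sess$max_span_achieved < 3]
  reason_pid[below3[is.na(reason_pid[below3])]] <- "span_below_three"

  reason <- reason_pid[tr$participant_id]
  reason[is.na(reason) & tr$adjudication != "correct"] <- "incorrect_trial"

  keep <- is.na(reason)
  n_by_pid <- table(tr$participant_id[keep])
  few <- names(n_by_pid)[n_by_pid < 2]
  reason[is.na(reason) & tr$participant_id %in% few] <- "insufficient_trials"
  keep <- is.na(reason)

  excl <- data.frame(participant_id = tr$participant_id[!keep],
                     trial_id = tr$trial_id[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  inc <- tr[keep, , drop = FALSE]
  lab <- compute_load(inc$span, inc$max_span_attempted, threshold)
  inc$relative_load <- lab$relative_load
  inc$is_high <- lab$is_high
  feats <- cohort$features[match(inc$trial_id, rownames(cohort$features)), ,
                           drop = FALSE]
  structure(list(trials = inc, features = feats, features_norm = NULL,
                 exclusions = excl, threshold = threshold),
            class = "vocload_analysis")
}

#' Within-subject normalization of trial features
#'
#' For every participant and feature, subtracts that participant's mean over
#' their included trials and divides by their sample SD (denominator n-1), so
#' normalized features express trial-by-trial deviations from the
#' participant's own vocal baseline; speaker and device offsets cancel
#' exactly. Features with zero within-participant SD map to 0.
#'
#' @param ds A `vocload_analysis` from [filter_cohort()].
#' @param center_only If `TRUE`, centre without scaling.
#' @return `ds` with `features_norm` filled in.
#' @export
normalize_within_subject <- function(ds, center_only = FALSE) {
  X <- ds$features
  pid <- ds$trials$participant_id
  n <- table(pid)[unique(pid)]
  if (any(n < 2))
    verr("invalid_parameter",
         "every participant needs >= 2 included trials (run filter_cohort)")
  g <- factor(pid, levels = unique(pid))
  cnt <- as.vector(table(g))
  mu <- rowsum(X, g) / cnt
  ctr <- X - mu[as.integer(g), , drop = FALSE]
  if (center_only) {
    ds$features_norm <- ctr
    return(ds)
  }
  sdv <- sqrt(rowsum(ctr^2, g) / (cnt - 1))
  sd_rows <- sdv[as.integer(g), , drop = FALSE]
  Z <- ifelse(sd_rows > 0, ctr / sd_rows, 0)
  dimnames(Z) <- dimnames(X)
  ds$features_norm <- Z
  ds
}

#' Write the exclusion log to CSV
#'
#' @param ds A `vocload_analysis`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(ds, path) {
  write.csv(ds$exclusions, path, row.names = FALSE)
  invisible(path)
}
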