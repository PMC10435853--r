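#' Configuration of the adaptive backwards digit span task
#'
#' The task starts at a two-digit sequence, adds one digit after every
#' correct answer up to eight, and terminates early after
#' `consecutive_fail_limit` consecutive failures at one span. The response
#' window for a trial at span `s` closes after `silence_coeffs[1] * s +
#' silence_coeffs[2]` seconds of contiguous silence or after an absolute
#' duration of `absolute_coeffs[1] * s + absolute_coeffs[2]` seconds.
#'
#' @param start_span First sequence length presented (digits).
#' @param max_span Longest sequence length presented (digits).
#' @param consecutive_fail_limit Consecutive failures at one span that end the
#'   session early.
#' @param silence_coeffs Numeric `(slope, intercept)` of the contiguous-silence
#'   window in seconds per digit and seconds.
#' @param absolute_coeffs Numeric `(slope, intercept)` of the absolute window.
#' @param digits_replace Sample sequence digits with replacement? Default
#'   `FALSE`: digits within a sequence are distinct, standard digit-span
#'   practice (feasible up to span 8 from the 10 digits).
#' @return An object of class `vocload_task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' response_window(4, cfg)
task_config <- function(start_span = 2L, max_span = 8L,
                        consecutive_fail_limit = 3L,
                        silence_coeffs = c(2.0, 2.0),
                        absolute_coeffs = c(2.5, 2.0),
                        digits_replace = FALSE) {
  start_span <- as.integer(start_span); max_span <- as.integer(max_span)
  if (start_span < 2L || start_span > max_span)
    verr("invalid_parameter", "need 2 <= start_span <= max_span (got %d, %d)",
         start_span, max_span)
  if (!digits_replace && max_span > 10L)
    verr("invalid_parameter", "max_span > 10 requires digits_replace = TRUE")
  if (consecutive_fail_limit < 1L)
    verr("invalid_parameter", "consecutive_fail_limit must be >= 1")
  if (any(c(silence_coeffs, absolute_coeffs) <= 0))
    verr("invalid_parameter", "window coefficients must be positive")
  structure(list(start_span = start_span, max_span = max_span,
                 consecutive_fail_limit = as.integer(consecutive_fail_limit),
                 silence_coeffs = as.numeric(silence_coeffs),
                 absolute_coeffs = as.numeric(absolute_coeffs),
                 digits_replace = isTRUE(digits_replace)),
            class = "vocload_task_config")
}

#' Error model of one simulated speech-recognition engine
#'
#' Stand-in for a cloud ASR service: each digit of the spoken response is
#' independently deleted with probability `deletion_prob` or substituted by a
#' different digit with probability `per_digit_error_prob`; with probability
#' `no_output_prob` the engine returns no transcript at all.
#'
#' @param per_digit_error_prob Probability a digit is transcribed as a
#'   different digit.
#' @param deletion_prob Probability a digit is dropped from the transcript.
#' @param no_output_prob Probability the engine returns an empty transcript.
#' @return An object of class `vocload_asr_engine`.
#' @export
asr_engine <- function(per_digit_error_prob = 0, deletion_prob = 0,
                       no_output_prob = 0) {
  p <- c(per_digit_error_prob, deletion_prob, no_output_prob)
  if (any(p < 0) || any(p > 1))
    verr("invalid_parameter", "engine error probabilities must be in [0,1]")
  if (per_digit_error_prob + deletion_prob > 1)
    verr("invalid_parameter",
         "per-digit error modes must be mutually exclusive (sum <= 1)")
  structure(list(per_digit_error_prob = per_digit_error_prob,
                 deletion_prob = deletion_prob,
                 no_output_prob = no_output_prob),
            class = "vocload_asr_engine")
}

#' Default ensemble of simulated recognition engines
#'
#' Three engines (mirroring the multi-service scoring proxy the task was
#' administered with) sharing one error model; the default is error-free, so
#' the recognition layer is transparent unless error rates are requested.
#'
#' @param n Number of engines.
#' @param ... Passed to [asr_engine()].
#' @return List of `vocload_asr_engine`.
#' @export
default_engines <- function(n = 3L, ...) {
  rep(list(asr_engine(...)), n)
}

#' Random digit sequence for one trial
#'
#' Sequences are fully randomized so that a downstream classifier cannot learn
#' digit identities instead of load. Digits are drawn without replacement by
#' default (see [task_config()]).
#'
#' @param span Sequence length, 2..8.
#' @param replace Sample with replacement?
#' @return Integer vector of `span` digits in 0..9. Uses the current RNG
#'   stream.
#' @export
random_sequence <- function(span, replace = FALSE) {
  if (length(span) != 1L || is.na(span) || span < 2 || span > 8)
    verr("invalid_parameter", "span must be in [2, 8], got %s", span)
  sample(0:9, as.integer(span), replace = replace)
}

#' Response-window durations for a trial
#'
#' @param span Sequence length (digits).
#' @param cfg A [task_config()].
#' @return Named numeric `c(silence, absolute)` in seconds; under default
#'   coefficients `(2*span + 2, 2.5*span + 2)`.
#' @export
response_window <- function(span, cfg = task_config()) {
  if (any(span <= 0)) verr("invalid_parameter", "span must be positive")
  c(silence = cfg$silence_coeffs[1] * span + cfg$silence_coeffs[2],
    absolute = cfg$absolute_coeffs[1] * span + cfg$absolute_coeffs[2])
}

#' Simulate transcripts from an ensemble of recognition engines
#'
#' @param true_utterance Integer digit vector actually spoken.
#' @param engines List of [asr_engine()] error models.
#' @return List of integer digit vectors, one per engine; an engine that
#'   produced no output yields `integer(0)`. With all error probabilities zero
#'   every transcript equals `true_utterance`. Uses the current RNG stream.
#' @export
simulate_asr_ensemble <- function(true_utterance, engines) {
  if (length(engines) < 1L) verr("invalid_parameter", "need at least one engine")
  lapply(engines, function(e) {
    if (runif(1) < e$no_output_prob) return(integer(0))
    n <- length(true_utterance)
    if (n == 0L) return(integer(0))
    u <- runif(n)
    keep <- u >= e$deletion_prob
    sub <- u >= e$deletion_prob & u < e$deletion_prob + e$per_digit_error_prob
    out <- true_utterance
    if (any(sub))  # substitute with a uniformly random *different* digit
      out[sub] <- (out[sub] + sample(1:9, sum(sub), replace = TRUE)) %% 10L
    out[keep]
  })
}

#' Adjudicate one trial from ensemble transcripts and elapsed times
#'
#' Implements the recording-window closure rules: (1) correct if any engine's
#' transcript equals the reversed presented sequence; else (2) incorrect if at
#' least two engines agree on the same full-span wrong response; else a
#' silence or absolute timeout, whichever window was exceeded (silence takes
#' priority and is the fall-through when the simulator reports the window as
#' expired).
#'
#' @param transcripts List of integer digit vectors (possibly empty vectors).
#' @param presented_sequence Integer digit vector as presented.
#' @param elapsed_silence Contiguous silence observed, seconds.
#' @param elapsed_total Total window duration observed, seconds.
#' @param cfg A [task_config()].
#' @return One of `"correct"`, `"incorrect_agreed"`, `"silence_timeout"`,
#'   `"absolute_timeout"`.
#' @export
adjudicate_response <- function(transcripts, presented_sequence,
                                elapsed_silence, elapsed_total,
                                cfg = task_config()) {
  if (length(transcripts) < 1L)
    verr("invalid_parameter", "transcripts must be a non-empty list")
  target <- rev(presented_sequence)
  span <- length(presented_sequence)
  if (any(vapply(transcripts, function(t) identical(as.integer(t), as.integer(target)),
                 logical(1))))
    return("correct")
  full <- transcripts[vapply(transcripts, length, integer(1)) == span]
  if (length(full) >= 2L) {
    keys <- vapply(full, paste, character(1), collapse = "")
    if (any(duplicated(keys))) return("incorrect_agreed")
  }
  win <- response_window(span, cfg)
  if (elapsed_silence >= win[["silence"]]) return("silence_timeout")
  if (elapsed_total >= win[["absolute"]]) return("absolute_timeout")
  "silence_timeout"  # window stays open until the silence condition closes it
}

# Fresh session state at the start of a run.
new_session_state <- function(cfg) {
  list(span = cfg$start_span, fails = 0L, max_span_attempted = cfg$start_span,
       max_span_achieved = 0L, terminated_early = FALSE, complete = FALSE)
}

#' Advance the adaptive staircase by one adjudicated trial
#'
#' A correct answer moves to the next span (or completes the session at the
#' maximum span) and resets the consecutive-failure counter; any other
#' outcome (including timeouts) counts as a failure at the same span, and the
#' session terminates early when the counter reaches the configured limit.
#'
#' @param state Session state as produced by [run_session()] internals.
#' @param outcome Adjudication string from [adjudicate_response()].
#' @param cfg A [task_config()].
#' @return Updated state list with fields `span`, `fails`,
#'   `max_span_attempted`, `max_span_achieved`, `terminated_early`, `complete`.
#' @export
advance_session <- function(state, outcome, cfg = task_config()) {
  if (isTRUE(state$terminated_early) || isTRUE(state$complete))
    verr("state", "cannot advance a finished session")
  if (identical(outcome, "correct")) {
    state$max_span_achieved <- state$span
    state$fails <- 0L
    if (state$span >= cfg$max_span) state$complete <- TRUE
    else {
      state$span <- state$span + 1L
      state$max_span_attempted <- state$span
    }
  } else {
    state$fails <- state$fails + 1L
    if (state$fails >= cfg$consecutive_fail_limit) state$terminated_early <- TRUE
  }
  state
}

# Simulated speaker: logistic item-response success model, and on failure a
# one-digit substitution of the correct reversal (full span, so two engines
# can agree on the wrong answer).
speaker_response <- function(presented, ability, tau) {
  target <- rev(presented)
  if (runif(1) < plogis((ability - length(presented)) / tau))
    return(list(spoken = target, intended_correct = TRUE))
  pos <- sample.int(length(target), 1L)
  target[pos] <- (target[pos] + sample(1:9, 1L)) %% 10L
  list(spoken = target, intended_correct = FALSE)
}

#' Run one full adaptive digit-span session for a simulated participant
#'
#' Presents randomized sequences, simulates a speaker with per-attempt success
#' probability `plogis((ability - span) / tau)`, passes the spoken response
#' through the recognition-engine ensemble, adjudicates, and advances the
#' staircase until completion or early termination.
#'
#' @param participant List or one-row data frame with at least `id` and
#'   `ability` (in digits).
#' @param cfg A [task_config()].
#' @param engines List of [asr_engine()] models.
#' @param tau Logistic scale of the speaker success model, digits.
#' @param seed Optional integer; when given the session is reproducible and
#'   the caller's RNG stream is untouched.
#' @return A `vocload_session`: list with `participant_id`, `trials` (one row
#'   per trial), `max_span_attempted`, `max_span_achieved`,
#'   `terminated_early`.
#' @export
#' @examples
#' s <- run_session(list(id = "P1", ability = 6), seed = 1)
#' s$max_span_achieved
run_session <- function(participant, cfg = task_config(),
                        engines = default_engines(), tau = 0.7, seed = NULL) {
  if (is.null(participant$ability) || is.na(participant$ability))
    verr("invalid_parameter", "participant needs a valid ability parameter")
  with_seed(seed, {
    state <- new_session_state(cfg)
    rows <- list()
    attempt <- 1L
    while (!state$terminated_early && !state$complete) {
      span <- state$span
      presented <- random_sequence(span, replace = cfg$digits_replace)
      resp <- speaker_response(presented, participant$ability, tau)
      transcripts <- simulate_asr_ensemble(resp$spoken, engines)
      win <- response_window(span, cfg)
      # The window closes as soon as a transcript condition resolves; if none
      # does, the silence clock runs out.
      latency <- runif(1, 1, 2) + 0.3 * span
      resolved <- adjudicate_response(transcripts, presented,
                                      elapsed_silence = 0,
                                      elapsed_total = latency, cfg = cfg)
      if (resolved %in% c("correct", "incorrect_agreed")) {
        el_sil <- 0; el_tot <- min(latency, win[["absolute"]])
      } else {
        el_sil <- win[["silence"]]
        el_tot <- min(latency + win[["silence"]], win[["absolute"]])
      }
      outcome <- adjudicate_response(transcripts, presented, el_sil, el_tot, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participant$id, span = span, attempt_index = attempt,
        presented_sequence = paste(presented, collapse = ""),
        spoken_response = paste(resp$spoken, collapse = ""),
        adjudication = outcome,
        is_correct = identical(outcome, "correct") &&
          identical(resp$spoken, rev(presented)),
        window_silence_s = win[["silence"]], window_absolute_s = win[["absolute"]],
        stringsAsFactors = FALSE)
      prev_span <- state$span
      state <- advance_session(state, outcome, cfg)
      attempt <- if (state$span == prev_span) attempt + 1L else 1L
    }
    structure(list(participant_id = participant$id,
                   trials = do.call(rbind, rows),
                   max_span_attempted = state$max_span_attempted,
                   max_span_achieved = state$max_span_achieved,
                   terminated_early = state$terminated_early),
              class = "vocload_session")
  })
}

#' Write session logs to CSV
#'
#' @param sessions List of `vocload_session` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path) {
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
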