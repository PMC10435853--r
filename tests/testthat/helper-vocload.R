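# Shared fixtures. Heavy objects (calibrations, the study-size cohort) are
# memoized so every test file reuses one build.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Ability parameters calibrated to the published cohort statistics.
fix_ability <- function() memo("ability", function() {
  calibrate_ability(n_sim = 5000, seed = 11)
})

# Study-size pipeline: skeleton-calibrated effect, 2,764-participant cohort
# with 300 features, filter/normalize/split, gradient boosting, evaluations.
fix_full_run <- function() memo("full_run", function() {
  ab <- fix_ability()
  base <- generator_config(
    n_participants = 2764, n_features = 300, n_informative = 10,
    ability_mean = ab[["ability_mean"]], ability_sd = ab[["ability_sd"]],
    intercept_sd = 2, noise_sd = 1, seed = 101)
  skel_cfg <- base; skel_cfg$n_features <- 2L; skel_cfg$n_informative <- 1L
  skeleton <- generate_cohort(skel_cfg)
  beta <- calibrate_effect(0.98, 4, skeleton, base, seed = 7)
  cfg <- base; cfg$effect_magnitude <- as.numeric(beta)
  cohort <- generate_cohort(cfg)
  ds <- normalize_within_subject(filter_cohort(cohort))
  split <- split_participants(unique(ds$trials$participant_id), seed = 5)
  sel <- ds$trials$participant_id %in% names(split)[split == "train"]
  gb <- train_classifier(classifier_spec("gradient_boosting", seed = 5),
                         ds$features_norm[sel, ], ds$trials$is_high[sel])
  list(cfg = cfg, beta = beta, cohort = cohort, ds = ds, split = split,
       gb = gb,
       ev_test = evaluate_subset(gb, ds, split, "test", "all"),
       ev_validate = evaluate_subset(gb, ds, split, "validate", "all"),
       ev_span4 = evaluate_subset(gb, ds, split, "validate", 4))
})

# Small calibrated cohort for model-level tests: 150 participants, 60
# features, strong load effect.
fix_small_run <- function() memo("small_run", function() {
  ab <- fix_ability()
  cfg <- generator_config(
    n_participants = 150, n_features = 60, n_informative = 6,
    ability_mean = ab[["ability_mean"]], ability_sd = ab[["ability_sd"]],
    effect_magnitude = 20, intercept_sd = 2, noise_sd = 1, seed = 202)
  cohort <- generate_cohort(cfg)
  ds <- normalize_within_subject(filter_cohort(cohort))
  split <- split_participants(unique(ds$trials$participant_id), seed = 9)
  sel <- ds$trials$participant_id %in% names(split)[split == "train"]
  gb <- train_classifier(classifier_spec("gradient_boosting", seed = 9),
                         ds$features_norm[sel, ], ds$trials$is_high[sel])
  list(cfg = cfg, cohort = cohort, ds = ds, split = split, gb = gb)
})

# Hand-built minimal cohort object for exact filtering/labeling assertions.
# P1: 5 of 7 trials correct, max achieved 6. P2: all incorrect. P3: max
# achieved 2. P4: achieved 3 but only one correct trial (as from imported
# data that started above span 2), exercising the insufficient-trials rule.
fix_handmade_cohort <- function() {
  mk <- function(pid, spans, correct) {
    data.frame(participant_id = pid, span = spans,
               attempt_index = seq_along(spans),
               presented_sequence = "00", spoken_response = "00",
               adjudication = ifelse(correct, "correct", "incorrect_agreed"),
               is_correct = correct, window_silence_s = 0,
               window_absolute_s = 0, stringsAsFactors = FALSE)
  }
  trials <- rbind(
    mk("P1", c(2, 3, 4, 4, 5, 6, 7), c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)),
    mk("P2", c(2, 2, 2), c(FALSE, FALSE, FALSE)),
    mk("P3", c(2, 3, 3, 3), c(TRUE, FALSE, FALSE, FALSE)),
    mk("P4", c(3, 4, 4, 4), c(TRUE, FALSE, FALSE, FALSE)))
  sess <- data.frame(
    participant_id = c("P1", "P2", "P3", "P4"),
    max_span_attempted = c(7, 2, 3, 4),
    max_span_achieved = c(6, 0, 2, 3),
    terminated_early = c(TRUE, TRUE, TRUE, TRUE),
    n_trials = c(7, 3, 4, 4), stringsAsFactors = FALSE)
  trials$trial_id <- sprintf("%s_T%02d", trials$participant_id,
                             stats::ave(seq_len(nrow(trials)),
                                        trials$participant_id, FUN = seq_along))
  trials$max_span_attempted <-
    sess$max_span_attempted[match(trials$participant_id, sess$participant_id)]
  trials$relative_load <- trials$span / trials$max_span_attempted
  set.seed(1)
  features <- matrix(rnorm(nrow(trials) * 3), nrow(trials),
                     dimnames = list(trials$trial_id, c("f1", "f2", "f3")))
  structure(list(participants = list(info = data.frame(id = sess$participant_id)),
                 sessions = sess, trials = trials, features = features),
            class = "vocload_cohort")
}

# Brute-force Mann-Whitney concordance (ties = 1/2), the AUC oracle.
concordance_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  g <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(g)
}

# Two-Gaussian-blob toy set, linearly separable at distance d.
toy_blobs <- function(n = 60, d = 10, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = d), ncol = p))
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = rep(c(FALSE, TRUE), each = n / 2))
}
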