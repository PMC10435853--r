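#' ROC curve points from scores and labels
#'
#' Sweeps thresholds over the unique scores in decreasing order (a point's
#' threshold classifies scores `>= threshold` as positive); tied scores are
#' grouped at one threshold, which with trapezoidal integration gives tied
#' pairs half credit, so the AUC equals the Mann-Whitney concordance.
#'
#' @param scores Numeric scores (higher = more likely high load).
#' @param labels Logical (or 0/1) true labels.
#' @return Data frame `(fpr, tpr, threshold)` starting at (0, 0) with
#'   threshold `Inf` and ending at (1, 1); both coordinates non-decreasing.
#' @export
#' @examples
#' roc_points(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) verr("schema", "length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    verr("invalid_parameter", "both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
             threshold = c(Inf, s[last]))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc Data frame from [roc_points()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Precision, recall, F1 and accuracy from hard predictions
#'
#' Per-class precision/recall/F1 are computed from the 2x2 confusion matrix
#' and combined by a support-weighted average (macro averaging by flag);
#' accuracy is the trace fraction. A class never predicted has precision 0.
#'
#' @param predicted,actual Logical (or 0/1) vectors of equal length.
#' @param average `"weighted"` (by class support in `actual`) or `"macro"`.
#' @return List with `precision`, `recall`, `f1`, `accuracy`, `per_class`
#'   (data frame) and `confusion` (2x2 matrix).
#' @export
classification_report <- function(predicted, actual,
                                  average = c("weighted", "macro")) {
  average <- match.arg(average)
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  if (length(predicted) != length(actual)) verr("schema", "length mismatch")
  if (length(unique(actual)) < 2L)
    verr("invalid_parameter", "actual labels contain a single class")
  lv <- c(FALSE, TRUE)
  cm <- table(factor(actual, lv), factor(predicted, lv))  # rows=actual
  per <- lapply(1:2, function(i) {
    tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1, support = tp + fn)
  })
  per <- as.data.frame(do.call(rbind, per))
  per$class <- c("low", "high")
  w <- if (average == "weighted") per$support / sum(per$support) else c(.5, .5)
  list(precision = sum(w * per$precision), recall = sum(w * per$recall),
       f1 = sum(w * per$f1), accuracy = sum(diag(cm)) / sum(cm),
       per_class = per, confusion = cm)
}

#' Evaluate a model on one participant subset, optionally span-restricted
#'
#' Scores only trials whose participants belong to the requested subset (a
#' leakage audit lives in the returned counts) and optionally restricts to a
#' single span; the published validation analysis restricts to span 4, the
#' median span, where utterance length no longer separates high from low
#' load.
#'
#' @param model A `vocload_model`.
#' @param ds A normalized `vocload_analysis`.
#' @param split A [split_participants()] assignment.
#' @param subset `"train"`, `"test"` or `"validate"`.
#' @param span_filter `"all"` or a single span (integer).
#' @return A `vocload_eval`: subset/filter, `precision`, `recall`, `f1`,
#'   `accuracy` (support-weighted), `auc`, `roc` data frame, `n_high`,
#'   `n_low`, and the scored `predictions` data frame.
#' @export
evaluate_subset <- function(model, ds, split, subset = "validate",
                            span_filter = "all") {
  if (is.null(ds$features_norm))
    verr("invalid_parameter", "run normalize_within_subject first")
  pids <- names(split)[split == subset]
  sel <- ds$trials$participant_id %in% pids
  if (!identical(span_filter, "all")) sel <- sel & ds$trials$span == span_filter
  if (!any(sel)) verr("degenerate_subset", "no trials in subset after filtering")
  tr <- ds$trials[sel, , drop = FALSE]
  y <- tr$is_high
  if (length(unique(y)) < 2L)
    verr("degenerate_subset",
         "single-class subset after filtering (n_high=%d, n_low=%d)",
         sum(y), sum(!y))
  p <- score_trials(model, ds$features_norm[sel, , drop = FALSE])
  roc <- roc_points(p, y)
  rep <- classification_report(p > 0.5, y)
  structure(list(subset = subset, span_filter = span_filter,
                 precision = rep$precision, recall = rep$recall, f1 = rep$f1,
                 accuracy = rep$accuracy, auc = auc_trapezoid(roc), roc = roc,
                 n_high = sum(y), n_low = sum(!y),
                 predictions = data.frame(trial_id = tr$trial_id,
                                          participant_id = tr$participant_id,
                                          subset = subset, span = tr$span,
                                          relative_load = tr$relative_load,
                                          probability = p,
                                          predicted = p > 0.5, actual = y,
                                          stringsAsFactors = FALSE)),
            class = "vocload_eval")
}

#' @export
print.vocload_eval <- function(x, ...) {
  cat(sprintf(
    "<vocload_eval> %s (spans: %s) | n=%d (high %d / low %d)\n  precision %.3f  recall %.3f  f1 %.3f  accuracy %.3f  AUC %.3f\n",
    x$subset, paste(x$span_filter, collapse = ","),
    x$n_high + x$n_low, x$n_high, x$n_low,
    x$precision, x$recall, x$f1, x$accuracy, x$auc))
  invisible(x)
}

#' Probability-versus-load diagnostic table
#'
#' Long-format table relating the model's probability of high load to the
#' observed relative load and span on a scored subset, for the standard
#' scatter diagnostics (load boundary 0.6, decision boundary 0.5 carried as
#' attributes).
#'
#' @param model A `vocload_model`.
#' @param ds A normalized `vocload_analysis`.
#' @param split A [split_participants()] assignment.
#' @param subset Subset to score (default `"validate"`).
#' @return Data frame `(relative_load, span, probability, is_high)` with
#'   attributes `load_boundary` and `decision_boundary`.
#' @export
probability_load_diagnostic <- function(model, ds, split, subset = "validate") {
  ev <- evaluate_subset(model, ds, split, subset, "all")
  pr <- ev$predictions
  structure(data.frame(relative_load = pr$relative_load, span = pr$span,
                       probability = pr$probability, is_high = pr$actual),
            load_boundary = ds$threshold, decision_boundary = 0.5)
}

#' Permutation null of the classifier AUC
#'
#' Permutes high/low labels within each participant (respecting the clustered
#' structure), retrains the classifier on the train subset and re-evaluates
#' on the requested subset, `n_permutations` times. The resulting AUC
#' distribution should be centred at 0.5; the observed AUC on unpermuted
#' labels serves as the positive control.
#'
#' @param ds A normalized `vocload_analysis`.
#' @param split A [split_participants()] assignment.
#' @param spec A [classifier_spec()].
#' @param n_permutations Number of permutations (>= 20).
#' @param subset Evaluation subset (default `"test"`).
#' @param seed Permutation seed.
#' @return List with `mean`, `q025`, `q975` and the vector `aucs`.
#' @export
permutation_null <- function(ds, split, spec, n_permutations = 50L,
                             subset = "test", seed = 1L) {
  if (n_permutations < 20L) verr("invalid_parameter", "need >= 20 permutations")
  tr_sel <- ds$trials$participant_id %in% names(split)[split == "train"]
  ev_sel <- ds$trials$participant_id %in% names(split)[split == subset]
  X_tr <- ds$features_norm[tr_sel, , drop = FALSE]
  X_ev <- ds$features_norm[ev_sel, , drop = FALSE]
  pid <- ds$trials$participant_id
  y <- ds$trials$is_high
  aucs <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    yp <- stats::ave(as.numeric(y), pid, FUN = sample) > 0.5
    m <- train_classifier(spec, X_tr, yp[tr_sel])
    auc_trapezoid(roc_points(score_trials(m, X_ev), yp[ev_sel]))
  }, numeric(1)))
  list(mean = mean(aucs), q025 = unname(quantile(aucs, 0.025)),
       q975 = unname(quantile(aucs, 0.975)), aucs = aucs)
}

#' Sample size for estimating sensitivity and specificity (Buderer)
#'
#' Required cohort size so that a two-sided `1 - alpha` confidence interval
#' for sensitivity (and specificity) has half-width `ci_halfwidth`:
#' `n = z^2 * p * (1 - p) / w^2` cases are needed, inflated by the prevalence
#' (for sensitivity) or its complement (for specificity); the larger of the
#' two totals is returned.
#'
#' @param sensitivity,specificity Anticipated proportions in (0, 1).
#' @param prevalence Prevalence of the positive condition in (0, 1).
#' @param ci_halfwidth Confidence-interval half-width `w` in (0, 1).
#' @param alpha Two-sided significance level.
#' @return List with `n_sensitivity`, `n_specificity` (required totals) and
#'   `required` (their maximum).
#' @export
#' @examples
#' buderer_sample_size(0.7, 0.7, prevalence = 0.5, ci_halfwidth = 0.05)
buderer_sample_size <- function(sensitivity, specificity, prevalence,
                                ci_halfwidth, alpha = 0.05) {
  p <- c(sensitivity, specificity, prevalence, ci_halfwidth, alpha)
  if (any(p <= 0) || any(p >= 1))
    verr("invalid_parameter", "all inputs must be in (0, 1)")
  z <- qnorm(1 - alpha / 2)
  n_se <- z^2 * sensitivity * (1 - sensitivity) / ci_halfwidth^2
  n_sp <- z^2 * specificity * (1 - specificity) / ci_halfwidth^2
  list(n_sensitivity = ceiling(n_se / prevalence),
       n_specificity = ceiling(n_sp / (1 - prevalence)),
       required = max(ceiling(n_se / prevalence),
                      ceiling(n_sp / (1 - prevalence))))
}
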