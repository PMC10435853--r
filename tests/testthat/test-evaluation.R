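test_that("ROC curves satisfy their boundary and monotonicity contract", {
  roc <- roc_points(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(tail(roc$fpr, 1), 1); expect_equal(tail(roc$tpr, 1), 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect ranking corner
  expect_equal(auc_trapezoid(roc), 1.0)
  expect_equal(auc_trapezoid(roc_points(c(0.5, 0.5), c(TRUE, FALSE))), 0.5)
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)),
               class = "vocload_invalid_parameter")
  set.seed(2)
  r <- roc_points(rnorm(50), sample(c(TRUE, FALSE), 50, replace = TRUE))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("trapezoidal AUC equals brute-force concordance, including ties", {
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:200, 1)
    scores <- round(rnorm(n), 1)  # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auc_trapezoid(roc_points(scores, labels)),
                 concordance_auc(scores, labels), tolerance = 1e-12)
  }
  # agreement with an independent reference implementation
  skip_if_not_installed("pROC")
  set.seed(99)
  s <- rnorm(150); l <- runif(150) < 0.5
  expect_equal(auc_trapezoid(roc_points(s, l)),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("random balanced scores give near-diagonal AUC", {
  set.seed(7)
  auc <- auc_trapezoid(roc_points(runif(1000), rep(c(TRUE, FALSE), 500)))
  expect_lt(abs(auc - 0.5), 0.04)
})

test_that("classification metrics match the 2x2 confusion-table arithmetic", {
  rep_perfect <- classification_report(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(unlist(rep_perfect[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
  all_pos <- classification_report(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(all_pos$accuracy, 0.5)
  high <- all_pos$per_class[all_pos$per_class$class == "high", ]
  expect_equal(high$recall, 1.0)
  expect_equal(high$precision, 0.5)
  # direct 2x2 oracle at a random confusion structure
  set.seed(12)
  act <- runif(200) < 0.45; prd <- xor(act, runif(200) < 0.3)
  r <- classification_report(prd, act)
  tp <- sum(prd & act); fp <- sum(prd & !act); fn <- sum(!prd & act)
  tn <- sum(!prd & !act)
  prec_hi <- tp / (tp + fp); rec_hi <- tp / (tp + fn)
  prec_lo <- tn / (tn + fn); rec_lo <- tn / (tn + fp)
  w_hi <- mean(act); w_lo <- 1 - w_hi
  expect_equal(r$accuracy, (tp + tn) / 200)
  expect_equal(r$precision, w_lo * prec_lo + w_hi * prec_hi)
  expect_equal(r$recall, w_lo * rec_lo + w_hi * rec_hi)
  # row-order invariance
  o <- sample(200)
  expect_equal(classification_report(prd[o], act[o])$f1, r$f1)
  # macro flag averages classes equally
  rm <- classification_report(prd, act, average = "macro")
  expect_equal(rm$recall, (rec_lo + rec_hi) / 2)
  expect_error(classification_report(TRUE, c(TRUE, FALSE)),
               class = "vocload_schema")
})

test_that("subset evaluation filters by participant and span without leakage", {
  run <- fix_small_run()
  ev4 <- evaluate_subset(run$gb, run$ds, run$split, "validate", 4)
  expect_true(all(ev4$predictions$span == 4))
  n_span4 <- sum(run$ds$trials$span == 4 &
                   run$ds$trials$participant_id %in%
                     names(run$split)[run$split == "validate"])
  expect_equal(ev4$n_high + ev4$n_low, n_span4)
  vp <- names(run$split)[run$split == "validate"]
  expect_true(all(ev4$predictions$participant_id %in% vp))
  expect_error(evaluate_subset(run$gb, run$ds, run$split, "validate", 2),
               class = "vocload_degenerate_subset")  # span-2 trials are all low
})

test_that("probability-load diagnostics separate high from low load", {
  run <- fix_small_run()
  d <- probability_load_diagnostic(run$gb, run$ds, run$split, "validate")
  expect_identical(d$is_high, d$relative_load > attr(d, "load_boundary"))
  expect_gt(mean(d$probability[d$is_high]), mean(d$probability[!d$is_high]))
  expect_equal(attr(d, "decision_boundary"), 0.5)
  # short utterances near a participant's ceiling still read as high load
  short_high <- d$span <= 3 & d$is_high
  if (any(short_high)) expect_gt(mean(d$probability[short_high]), 0.5)
})

test_that("the Buderer formula reproduces its worked examples", {
  n5 <- buderer_sample_size(0.7, 0.7, prevalence = 0.5, ci_halfwidth = 0.05)
  expect_equal(n5$required, 646)
  expect_equal(n5$n_sensitivity, 646)
  n10 <- buderer_sample_size(0.7, 0.7, prevalence = 0.5, ci_halfwidth = 0.10)
  expect_equal(n10$required, 162)
  # as prevalence -> 1 the sensitivity arm needs no inflation
  n99 <- buderer_sample_size(0.7, 0.7, prevalence = 0.99, ci_halfwidth = 0.05)
  expect_equal(n99$n_sensitivity, ceiling(qnorm(0.975)^2 * 0.21 / 0.0025 / 0.99))
  expect_gt(n99$n_specificity, n99$n_sensitivity)
  expect_error(buderer_sample_size(0.7, 0.7, 0.5, 0),
               class = "vocload_invalid_parameter")
})
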