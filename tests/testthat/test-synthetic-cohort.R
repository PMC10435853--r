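test_that("participant sampling matches its distributional contract", {
  cfg0 <- generator_config(n_participants = 50, ability_mean = 6, ability_sd = 0)
  expect_true(all(sample_participants(cfg0)$info$ability == 6))
  cfg <- generator_config(n_participants = 10000, ability_mean = 6,
                          ability_sd = 1, n_features = 3, n_informative = 1,
                          seed = 5)
  p <- sample_participants(cfg)
  expect_lt(abs(mean(p$info$ability) - 6), 0.03)
  expect_identical(sample_participants(cfg), p)
  expect_error(generator_config(n_participants = 0),
               class = "vocload_invalid_parameter")
})

test_that("trial features are intercept + load shift along a unit direction + noise", {
  cfg <- generator_config(n_participants = 2, n_features = 40, n_informative = 5,
                          effect_magnitude = 8, intercept_sd = 0, noise_sd = 0,
                          seed = 3)
  dir <- vocload:::feature_direction(cfg)
  expect_equal(sum(dir$u^2), 1)
  x <- generate_trial_features(0.5, numeric(40), cfg)
  expect_equal(unname(x[dir$idx]), 8 * 0.5 * dir$u)
  expect_true(all(x[-dir$idx] == 0))
  expect_error(generate_trial_features(0, numeric(40), cfg),
               class = "vocload_invalid_parameter")
  expect_error(generate_trial_features(1.2, numeric(40), cfg),
               class = "vocload_invalid_parameter")
})

test_that("oracle linear score AUC between two fixed loads matches the Gaussian closed form", {
  cfg <- generator_config(n_participants = 1, n_features = 30, n_informative = 4,
                          effect_magnitude = 3, intercept_sd = 0, noise_sd = 1,
                          seed = 6)
  dir <- vocload:::feature_direction(cfg)
  l1 <- 0.4; l2 <- 0.9; n <- 4000
  set.seed(61)
  score <- function(load) vapply(seq_len(n), function(i)
    sum(generate_trial_features(load, numeric(30), cfg, dir)[dir$idx] * dir$u),
    numeric(1))
  s <- c(score(l1), score(l2))
  lab <- rep(c(FALSE, TRUE), each = n)
  expected <- pnorm(cfg$effect_magnitude * (l2 - l1) / (cfg$noise_sd * sqrt(2)))
  expect_lt(abs(auc_trapezoid(roc_points(s, lab)) - expected), 0.02)
})

test_that("ability calibration round-trips its targets and errs on unreachable ones", {
  ab <- fix_ability()
  ach <- attr(ab, "achieved")
  expect_lt(abs(ach[["mean"]] - 6.34), 0.05)
  expect_lt(abs(ach[["sd"]] - 1.38), 0.1)
  expect_identical(ab, calibrate_ability(n_sim = 5000, seed = 11))
  expect_error(calibrate_ability(target_mean = 8), class = "vocload_no_solution")
  expect_error(calibrate_ability(target_mean = 2), class = "vocload_no_solution")
})

test_that("span SD grows with ability SD at fixed mean over a 3-point grid", {
  task <- task_config()
  set.seed(8)
  z <- rnorm(4000)
  U <- array(runif(4000 * 7 * 3), dim = c(4000, 7, 3))
  sds <- vapply(c(0.5, 1.5, 3), function(sig)
    sd(vocload:::simulate_max_spans(6.2, sig, 0.7, task, z, U)), numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("effect calibration hits the target oracle AUC, is monotone, and degenerates at 0.5", {
  run <- fix_full_run()
  skel_cfg <- run$cfg; skel_cfg$n_features <- 2L; skel_cfg$n_informative <- 1L
  skeleton <- generate_cohort(skel_cfg)
  expect_lt(abs(attr(run$beta, "oracle_auc") - 0.98), 0.005)
  # fresh-noise re-evaluation of the returned beta
  b2 <- calibrate_effect(0.98, 4, skeleton, run$cfg, seed = 99)
  expect_lt(abs(as.numeric(b2) - as.numeric(run$beta)) /
              as.numeric(run$beta), 0.1)
  b90 <- calibrate_effect(0.90, 4, skeleton, run$cfg, seed = 7)
  expect_lt(as.numeric(b90), as.numeric(run$beta))
  b_null <- calibrate_effect(0.501, 4, skeleton, run$cfg, seed = 7)
  expect_lt(as.numeric(b_null), 0.5)
  expect_error(calibrate_effect(0.4, 4, skeleton, run$cfg),
               class = "vocload_invalid_parameter")
})

test_that("cohort generation is reproducible and respects the ceiling", {
  cfg <- generator_config(n_participants = 10, n_features = 15, seed = 77)
  d1 <- write_cohort(generate_cohort(cfg), tempfile("coh1"))
  d2 <- write_cohort(generate_cohort(cfg), tempfile("coh2"))
  for (f in c("participants.csv", "trials.csv", "features.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  hi <- generator_config(n_participants = 6, n_features = 5, n_informative = 2,
                         ability_mean = 50, ability_sd = 0, seed = 2)
  co <- generate_cohort(hi)
  expect_true(all(co$sessions$max_span_achieved == 8))
  expect_true(all(co$sessions$n_trials == 7))
  expect_equal(nrow(co$features), nrow(co$trials))  # one vector per trial
})

test_that("within-subject normalization removes participant intercept scale entirely", {
  base <- generator_config(n_participants = 12, n_features = 10,
                           effect_magnitude = 5, intercept_sd = 0, seed = 21)
  big <- base; big$intercept_sd <- 5
  n0 <- normalize_within_subject(filter_cohort(generate_cohort(base)))
  n5 <- normalize_within_subject(filter_cohort(generate_cohort(big)))
  expect_equal(n0$features_norm, n5$features_norm, tolerance = 1e-10)
})

test_that("synthesized audio has one burst per digit and load-monotone pitch", {
  w <- synthesize_trial_audio(c(9, 3, 7, 2), load = 0.5)
  expect_lte(max(abs(w$samples)), 1)
  fr <- frame_signal(w$samples, w$sample_rate)
  active <- sqrt(rowMeans(fr^2)) > 0.05
  runs <- rle(active)
  expect_equal(sum(runs$values), 4)  # 4 bursts separated by silence
  f0_at <- function(load) {
    wv <- synthesize_trial_audio(c(1, 2, 3), load = load, base_f0 = 150)
    lld <- compute_llds(frame_signal(wv$samples, wv$sample_rate), wv$sample_rate)
    median(lld[lld[, "f0"] > 0, "f0"])
  }
  expect_gt(f0_at(1), f0_at(0.25))
  silent <- synthesize_trial_audio(c(1, 2), load = 0.5, amplitude = 0)
  expect_equal(sqrt(mean(silent$samples^2)), 0)
})
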