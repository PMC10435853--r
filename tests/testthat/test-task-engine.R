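test_that("response windows follow the 2s+2 / 2.5s+2 rules and their ordering", {
  cfg <- task_config()
  expect_equal(unname(response_window(2, cfg)), c(6, 7))
  expect_equal(unname(response_window(4, cfg)), c(10, 12))
  expect_equal(unname(response_window(8, cfg)), c(18, 22))
  w <- vapply(2:8, function(s) response_window(s, cfg), numeric(2))
  expect_true(all(diff(w["silence", ]) > 0) && all(diff(w["absolute", ]) > 0))
  expect_true(all(w["absolute", ] > w["silence", ]))
  expect_error(response_window(0, cfg), class = "vocload_invalid_parameter")
})

test_that("random sequences are distinct digits, in range, and uniform over pairs", {
  set.seed(1)
  s4 <- random_sequence(4)
  expect_length(s4, 4)
  expect_true(all(s4 %in% 0:9) && !anyDuplicated(s4))
  s8 <- random_sequence(8)
  expect_length(unique(s8), 8)
  expect_error(random_sequence(1), class = "vocload_invalid_parameter")
  expect_error(random_sequence(9), class = "vocload_invalid_parameter")
  # exact oracle: without replacement there are 90 equiprobable ordered pairs
  set.seed(42)
  draws <- replicate(10000, paste(random_sequence(2), collapse = ""))
  tab <- table(draws)
  expect_length(tab, 90)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)
})

test_that("ASR ensemble is transparent at zero error and matches the binomial closed form", {
  set.seed(3)
  u <- c(9, 3, 7, 2)
  expect_identical(simulate_asr_ensemble(u, default_engines(3)),
                   list(u, u, u))
  silent <- simulate_asr_ensemble(u, default_engines(2, no_output_prob = 1))
  expect_true(all(lengths(silent) == 0))
  expect_error(simulate_asr_ensemble(u, list()),
               class = "vocload_invalid_parameter")
  # P(fully correct transcript) = (1 - p)^span
  eng <- default_engines(1, per_digit_error_prob = 0.1)
  ok <- replicate(10000, identical(simulate_asr_ensemble(u, eng)[[1]], u))
  expect_equal(mean(ok), 0.9^4, tolerance = 0.03)
})

test_that("adjudication follows the four window-closure conditions in priority order", {
  cfg <- task_config()
  pres <- c(2, 7, 3)  # reversal is 3-7-2
  expect_identical(
    adjudicate_response(list(c(3, 7, 2), c(3, 7, 1), integer(0)), pres, 0, 3, cfg),
    "correct")
  expect_identical(
    adjudicate_response(list(c(3, 7, 1), c(3, 7, 1), c(2, 3, 4)), pres, 0, 3, cfg),
    "incorrect_agreed")
  expect_identical(
    adjudicate_response(list(c(3, 7), c(4), integer(0)), pres, 9, 9.5, cfg),
    "silence_timeout")  # 9 s silence > 2*3 + 2 = 8 s
  expect_identical(
    adjudicate_response(list(c(3, 7), c(4), integer(0)), pres, 2, 10, cfg),
    "absolute_timeout")  # 10 s total > 2.5*3 + 2 = 9.5 s
  # correct beats agreement; agreement needs full span
  expect_identical(
    adjudicate_response(list(c(3, 7, 2), c(3, 7, 1), c(3, 7, 1)), pres, 9, 10, cfg),
    "correct")
  expect_identical(
    adjudicate_response(list(c(3, 7), c(3, 7), integer(0)), pres, 9, 10, cfg),
    "silence_timeout")
})

test_that("staircase advances, resets, completes, and terminates after 3 consecutive fails", {
  cfg <- task_config()
  st <- list(span = 4L, fails = 2L, max_span_attempted = 4L,
             max_span_achieved = 3L, terminated_early = FALSE, complete = FALSE)
  expect_true(advance_session(st, "incorrect_agreed", cfg)$terminated_early)
  expect_true(advance_session(st, "silence_timeout", cfg)$terminated_early)
  up <- advance_session(st, "correct", cfg)
  expect_equal(c(up$span, up$fails, up$max_span_achieved), c(5, 0, 4))
  top <- list(span = 8L, fails = 0L, max_span_attempted = 8L,
              max_span_achieved = 7L, terminated_early = FALSE, complete = FALSE)
  done <- advance_session(top, "correct", cfg)
  expect_true(done$complete)
  expect_equal(done$max_span_achieved, 8)
  expect_error(advance_session(done, "correct", cfg), class = "vocload_state")
})

test_that("full sessions honor ceiling, floor, determinism and staircase invariants", {
  hi <- run_session(list(id = "A", ability = 1000), seed = 1)
  expect_equal(hi$max_span_achieved, 8)
  expect_equal(nrow(hi$trials), 7)
  expect_false(hi$terminated_early)
  lo <- run_session(list(id = "B", ability = -1000), seed = 2)
  expect_true(lo$terminated_early)
  expect_equal(nrow(lo$trials), 3)
  expect_true(all(lo$trials$span == 2))
  expect_lt(lo$max_span_achieved, 2)
  expect_identical(run_session(list(id = "C", ability = 6), seed = 7),
                   run_session(list(id = "C", ability = 6), seed = 7))
  eng <- default_engines(3, per_digit_error_prob = 0.05, deletion_prob = 0.02,
                         no_output_prob = 0.05)
  for (seed in 1:25) {
    s <- run_session(list(id = "D", ability = runif(1, 2, 9)),
                     engines = eng, seed = seed)
    expect_true(all(diff(s$trials$span) >= 0))
    expect_true(all(s$trials$span >= 2 & s$trials$span <= 8))
    fails_per_span <- tapply(s$trials$adjudication != "correct", s$trials$span, sum)
    expect_true(all(fails_per_span <= 3))
    expect_lte(s$max_span_achieved, s$max_span_attempted)
    if (s$terminated_early) {
      last3 <- tail(s$trials, 3)
      expect_length(unique(last3$span), 1)
      expect_true(all(last3$adjudication != "correct"))
    }
  }
})

test_that("per-span pass rate matches the 1-(1-p)^3 closed form", {
  ability <- 3.5; tau <- 0.7
  sessions <- lapply(1:1200, function(i)
    run_session(list(id = "E", ability = ability), tau = tau, seed = 10000 + i))
  for (span in 2:4) {
    attempted <- vapply(sessions, function(s) any(s$trials$span == span), logical(1))
    passed <- vapply(sessions, function(s) s$max_span_achieved >= span, logical(1))
    p <- plogis((ability - span) / tau)
    q <- 1 - (1 - p)^3
    n <- sum(attempted)
    expect_lt(abs(mean(passed[attempted]) - q), 4 * sqrt(q * (1 - q) / n) + 1e-3)
  }
})
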