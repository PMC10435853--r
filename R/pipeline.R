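#' Assemble (or load) a full experiment configuration
#'
#' An experiment config collects the generator, task, engine, labeling,
#' split, model and evaluation settings plus one global seed from which every
#' stage seed is derived. Accepts a YAML/JSON file path or a nested list;
#' missing blocks fall back to the documented defaults.
#'
#' @param config Path to a YAML or JSON config, or a nested list with any of
#'   the blocks `generator`, `task`, `engines`, `labeling`, `split`, `models`,
#'   `evaluation`, and a top-level `seed`.
#' @return A `vocload_experiment_config` list with fully resolved blocks.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  gen <- do.call(generator_config,
                 utils::modifyList(list(seed = derive_seed(seed, 3L)),
                                   as.list(config$generator %||% list())))
  task <- do.call(task_config, as.list(config$task %||% list()))
  engines <- if (is.null(config$engines)) default_engines()
  else lapply(config$engines, function(e) do.call(asr_engine, as.list(e)))
  labeling <- utils::modifyList(list(threshold = 0.6, center_only = FALSE),
                                as.list(config$labeling %||% list()))
  split <- utils::modifyList(list(fractions = c(0.6, 0.2, 0.2),
                                  seed = derive_seed(seed, 4L)),
                             as.list(config$split %||% list()))
  models <- config$models %||% list(
    list(family = "gradient_boosting"), list(family = "random_forest"),
    list(family = "linear_svm"), list(family = "gaussian_naive_bayes"),
    list(family = "logistic_regression"))
  models <- lapply(models, function(m) {
    if (inherits(m, "vocload_classifier_spec")) return(m)
    classifier_spec(m$family, m$hyperparameters %||% list(),
                    seed = m$seed %||% derive_seed(seed, 5L))
  })
  evaluation <- utils::modifyList(list(span_filter = 4L), # span-restricted check
                                  as.list(config$evaluation %||% list()))
  calib <- utils::modifyList(
    list(ability = FALSE, target_mean = 6.34, target_sd = 1.38,
         effect = FALSE, target_bayes_auc = 0.98, effect_span = 4L,
         n_sim = 5000L),
    as.list(config$calibration %||% list()))
  structure(list(seed = seed, generator = gen, task = task, engines = engines,
                 labeling = labeling, split = split, models = models,
                 evaluation = evaluation, calibration = calib,
                 write_features = config$write_features %||% TRUE),
            class = "vocload_experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full experiment: generate, label, normalize, split, train, evaluate
#'
#' Executes the whole analysis from one config: (optionally calibrated)
#' cohort generation, inclusion filtering and load labeling, within-subject
#' normalization, participant-wise 60/20/20 split, training of every
#' configured classifier, model comparison on the test subset, and a single
#' evaluation of the best test-AUC model (ties broken by accuracy, then by
#' config order) on the held-out validate subset, across all spans and
#' restricted to the configured span. Models that fail to converge are logged
#' and skipped, not reported. All artifacts (CSV tables, `report.json`,
#' `manifest.json`) are written to `out_dir`; a rerun with the same config
#' reproduces them byte for byte.
#'
#' @param config A [experiment_config()] input (path, list, or resolved
#'   config).
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly mirrored in `manifest.json`.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (inherits(config, "vocload_experiment_config")) config
  else experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[vocload] ", fmt), ...))

  gen <- cfg$generator
  if (isTRUE(cfg$calibration$ability)) {
    ab <- calibrate_ability(cfg$calibration$target_mean,
                            cfg$calibration$target_sd, tau = gen$tau,
                            task = cfg$task, n_sim = cfg$calibration$n_sim,
                            seed = derive_seed(cfg$seed, 6L))
    gen$ability_mean <- ab[["ability_mean"]]
    gen$ability_sd <- ab[["ability_sd"]]
    log_stage("calibrated ability: mean %.3f sd %.3f", gen$ability_mean,
              gen$ability_sd)
  }
  if (isTRUE(cfg$calibration$effect)) {
    skel_cfg <- gen; skel_cfg$n_features <- 2L; skel_cfg$n_informative <- 1L
    skeleton <- generate_cohort(skel_cfg, cfg$task, cfg$engines)
    gen$effect_magnitude <- as.numeric(calibrate_effect(
      cfg$calibration$target_bayes_auc, cfg$calibration$effect_span,
      skeleton, gen, threshold = cfg$labeling$threshold,
      seed = derive_seed(cfg$seed, 7L)))
    log_stage("calibrated effect magnitude: %.3f", gen$effect_magnitude)
  }

  log_stage("generating cohort of %d participants", gen$n_participants)
  cohort <- generate_cohort(gen, cfg$task, cfg$engines)
  write.csv(cohort$participants$info, file.path(out_dir, "participants.csv"),
            row.names = FALSE)
  write.csv(cohort$trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  if (isTRUE(cfg$write_features))
    write.csv(data.frame(trial_id = rownames(cohort$features), cohort$features,
                         check.names = FALSE),
              file.path(out_dir, "features.csv"), row.names = FALSE)

  ds <- filter_cohort(cohort, threshold = cfg$labeling$threshold)
  ds <- normalize_within_subject(ds, center_only = isTRUE(cfg$labeling$center_only))
  write_exclusions(ds, file.path(out_dir, "exclusions.csv"))
  log_stage("included %d trials, excluded %d", nrow(ds$trials),
            nrow(ds$exclusions))

  split <- split_participants(unique(ds$trials$participant_id),
                              fractions = cfg$split$fractions,
                              seed = cfg$split$seed)
  tr_sel <- ds$trials$participant_id %in% names(split)[split == "train"]
  X_tr <- ds$features_norm[tr_sel, , drop = FALSE]
  y_tr <- ds$trials$is_high[tr_sel]

  metrics <- list(); models <- list(); convergence <- list()
  for (spec in cfg$models) {
    log_stage("training %s", spec$family)
    m <- train_classifier(spec, X_tr, y_tr)
    convergence[[spec$family]] <- m$converged
    if (!m$converged) {
      log_stage("%s did not converge; not reported", spec$family)
      next
    }
    models[[spec$family]] <- m
    ev <- evaluate_subset(m, ds, split, "test", "all")
    metrics[[length(metrics) + 1L]] <- data.frame(
      model = spec$family, subset = "test", span_filter = "all",
      precision = ev$precision, recall = ev$recall, f1 = ev$f1,
      accuracy = ev$accuracy, auc = ev$auc, n_high = ev$n_high,
      n_low = ev$n_low, stringsAsFactors = FALSE)
  }
  if (length(models) == 0L) verr("state", "no model converged")
  test_tbl <- do.call(rbind, metrics)
  ord <- order(-test_tbl$auc, -test_tbl$accuracy,
               match(test_tbl$model, vapply(cfg$models, `[[`, "", "family")))
  best_name <- test_tbl$model[ord[1]]
  best <- models[[best_name]]
  log_stage("best model on test data: %s (AUC %.3f)", best_name,
            test_tbl$auc[ord[1]])

  # the validate subset is touched exactly once, by the best model
  ev_val <- evaluate_subset(best, ds, split, "validate", "all")
  ev_span <- tryCatch(
    evaluate_subset(best, ds, split, "validate", cfg$evaluation$span_filter),
    vocload_degenerate_subset = function(e) {
      log_stage("span-%s validate subset degenerate: %s",
                cfg$evaluation$span_filter, conditionMessage(e))
      NULL
    })
  val_tbl <- do.call(rbind, lapply(Filter(Negate(is.null),
                                          list(ev_val, ev_span)), function(ev)
    data.frame(model = best_name, subset = "validate",
               span_filter = as.character(ev$span_filter),
               precision = ev$precision, recall = ev$recall, f1 = ev$f1,
               accuracy = ev$accuracy, auc = ev$auc, n_high = ev$n_high,
               n_low = ev$n_low, stringsAsFactors = FALSE)))
  metrics_tbl <- rbind(test_tbl, val_tbl)
  write.csv(metrics_tbl, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(ev_val$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(ev_val$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
  diag <- probability_load_diagnostic(best, ds, split, "validate")
  write.csv(diag, file.path(out_dir, "fig3_data.csv"), row.names = FALSE)

  report <- list(best_model = best_name,
                 test = test_tbl,
                 validate = val_tbl,
                 disposition = split_disposition(ds, split))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- c("participants.csv", "trials.csv", "exclusions.csv", "metrics.csv",
             "predictions.csv", "roc.csv", "fig3_data.csv", "report.json")
  if (isTRUE(cfg$write_features)) files <- c(files, "features.csv")
  manifest <- list(
    seed = cfg$seed,
    generator = unclass(gen), task = unclass(cfg$task),
    counts = list(participants = gen$n_participants,
                  trials_total = nrow(cohort$trials),
                  trials_included = nrow(ds$trials),
                  trials_excluded = nrow(ds$exclusions)),
    convergence = convergence,
    best_model = best_name,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Table 2-style disposition of participants and trials across subsets.
split_disposition <- function(ds, split) {
  sub <- split[ds$trials$participant_id]
  do.call(rbind, lapply(c("train", "test", "validate"), function(s) {
    sel <- sub == s
    data.frame(subset = s,
               n_participants = sum(split == s),
               n_trials = sum(sel),
               n_low = sum(!ds$trials$is_high[sel]),
               n_high = sum(ds$trials$is_high[sel]),
               stringsAsFactors = FALSE)
  }))
}
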