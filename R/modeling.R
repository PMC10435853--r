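#' Participant-wise train/test/validate split
#'
#' Participants (never trials) are allocated to subsets by a seeded uniform
#' shuffle followed by a proportional cut, so no participant's trials straddle
#' subsets and the classifier is always evaluated on unseen voices.
#'
#' @param ids Character vector of participant ids.
#' @param fractions Numeric `(train, test, validate)` fractions summing to 1.
#' @param seed Shuffle seed.
#' @return Named character vector mapping id to `"train"`, `"test"` or
#'   `"validate"`, with the fractions and seed as attributes.
#' @export
#' @examples
#' table(split_participants(sprintf("P%02d", 1:10), seed = 1))
split_participants <- function(ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ids) < 5L) verr("invalid_parameter", "need at least 5 participants")
  if (anyDuplicated(ids)) verr("invalid_parameter", "duplicate participant ids")
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0))
    verr("invalid_parameter", "fractions must be positive and sum to 1")
  n <- length(ids)
  shuffled <- with_seed(seed, sample(ids))
  n_train <- round(fractions[1] * n)
  n_test <- round(fractions[2] * n)
  subset <- rep(c("train", "test", "validate"),
                c(n_train, n_test, n - n_train - n_test))
  structure(setNames(subset, shuffled)[ids],
            fractions = fractions, seed = seed)
}

#' Specification of one reference classifier
#'
#' Five families are supported, each with fixed published hyperparameters as
#' defaults: logistic regression (iterative convex fit, iteration cap 1000,
#' convergence surfaced honestly), Gaussian naive Bayes, linear-kernel SVM
#' (C = 15, stopping tolerance 0.01), random forest (100 trees, gini
#' impurity, minimum 10 samples to split, minimum leaf 8, feature fraction
#' 0.1 per split) and histogram gradient boosting (200 stages, learning rate
#' 0.1, depth 4, row subsample 0.75 without replacement, feature fraction
#' 0.65 per stage).
#'
#' @param family One of `"logistic_regression"`, `"gaussian_naive_bayes"`,
#'   `"linear_svm"`, `"random_forest"`, `"gradient_boosting"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed for stochastic families.
#' @return A `vocload_classifier_spec`.
#' @export
classifier_spec <- function(family = c("gradient_boosting", "random_forest",
                                       "linear_svm", "gaussian_naive_bayes",
                                       "logistic_regression"),
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic_regression = list(max_iter = 1000L),
    gaussian_naive_bayes = list(),
    linear_svm = list(C = 15.0, tolerance = 0.01),
    random_forest = list(n_trees = 100L, min_samples_split = 10L,
                         min_samples_leaf = 8L, max_features_frac = 0.1),
    gradient_boosting = list(n_stages = 200L, learning_rate = 0.1,
                             max_depth = 4L, min_samples_leaf = 10L,
                             min_samples_split = 6L, subsample = 0.75,
                             feature_fraction = 0.65))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp, seed = as.integer(seed)),
            class = "vocload_classifier_spec")
}

#' Train one classifier on normalized trial features
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (trials x features), typically
#'   within-subject normalized.
#' @param y Logical (or 0/1) high-load labels, one per row of `X`.
#' @return A `vocload_model`: `family`, opaque `fit`, `converged` flag (only
#'   logistic regression can fail to converge; the flag is honest and
#'   non-convergence is not an error), and training `metadata`. Use
#'   [score_trials()] to predict.
#' @export
train_classifier <- function(spec, X, y) {
  y <- as.logical(y)
  if (nrow(X) != length(y)) verr("schema", "X rows must match length(y)")
  if (length(unique(y)) < 2L)
    verr("invalid_parameter", "training labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  yf <- factor(ifelse(y, "high", "low"), levels = c("low", "high"))
  hp <- spec$hyperparameters
  converged <- TRUE
  fit <- with_seed(spec$seed, switch(spec$family,
    logistic_regression = {
      df <- data.frame(.y = yf, X, check.names = FALSE)
      sep_warn <- FALSE
      m <- withCallingHandlers(
        glm(.y ~ ., data = df, family = binomial(),
            control = glm.control(maxit = hp$max_iter)),
        warning = function(w) {
          sep_warn <<- TRUE; invokeRestart("muffleWarning")
        })
      converged <- m$converged && !sep_warn
      m
    },
    gaussian_naive_bayes = e1071::naiveBayes(x = X, y = yf),
    linear_svm = e1071::svm(x = X, y = yf, kernel = "linear", cost = hp$C,
                            tolerance = hp$tolerance, scale = FALSE,
                            probability = TRUE),
    random_forest = ranger::ranger(
      x = X, y = yf, num.trees = hp$n_trees, probability = TRUE,
      splitrule = "gini", min.node.size = hp$min_samples_split,
      min.bucket = hp$min_samples_leaf,
      mtry = max(1L, floor(hp$max_features_frac * ncol(X))),
      num.threads = 1L, seed = spec$seed),
    gradient_boosting = {
      d <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      # min_samples_leaf has no exact counterpart in xgboost; the logistic
      # hessian per row is <= 1/4, so min_child_weight = leaf/4 bounds it.
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$learning_rate,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$feature_fraction,
                      min_child_weight = hp$min_samples_leaf / 4,
                      tree_method = "hist", nthread = 1L, seed = spec$seed),
        data = d, nrounds = hp$n_stages, verbose = 0)
    }))
  structure(list(family = spec$family, fit = fit, converged = converged,
                 levels = c("low", "high"),
                 metadata = list(n_trials = nrow(X), n_features = ncol(X),
                                 feature_names = colnames(X), seed = spec$seed,
                                 hyperparameters = hp)),
            class = "vocload_model")
}

#' Predicted probability of high load for each trial
#'
#' @param model A `vocload_model`.
#' @param X Feature matrix with the training feature count.
#' @return Numeric vector of probabilities in `[0, 1]`; the hard prediction
#'   is `probability > 0.5` (the boundary itself is classed low).
#' @export
score_trials <- function(model, X) {
  if (ncol(X) != model$metadata$n_features)
    verr("schema", "feature count mismatch: %d vs %d trained",
         ncol(X), model$metadata$n_features)
  if (is.null(colnames(X))) colnames(X) <- model$metadata$feature_names
  p <- switch(model$family,
    logistic_regression = {
      df <- as.data.frame(X)
      as.numeric(predict(model$fit, newdata = df, type = "response"))
    },
    gaussian_naive_bayes =
      predict(model$fit, newdata = X, type = "raw")[, "high"],
    linear_svm = {
      pr <- predict(model$fit, newdata = X, probability = TRUE)
      attr(pr, "probabilities")[, "high"]
    },
    random_forest =
      predict(model$fit, data = X, num.threads = 1L)$predictions[, "high"],
    gradient_boosting = predict(model$fit, xgboost::xgb.DMatrix(X)))
  pmin(1, pmax(0, as.numeric(p)))
}

#' @export
print.vocload_model <- function(x, ...) {
  cat(sprintf("<vocload_model> %s | %d trials x %d features | converged: %s\n",
              x$family, x$metadata$n_trials, x$metadata$n_features,
              x$converged))
  invisible(x)
}
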