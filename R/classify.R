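#' Evaluation protocol for repeated holdout classification
#'
#' Mirrors the repeated 80/20 evaluation: per repetition the cohort is
#' split into training (80%) and held-out test (20%) participants; video
#' selection, imputation statistics and model fitting use the training set
#' only; accuracy is reported as 5-fold cross-validation on training and as
#' plain accuracy on the held-out set, averaged over repetitions.
#'
#' @param train_fraction fraction of participants in the training set.
#' @param n_repetitions number of random splits (default 18).
#' @param cv_folds folds for cross-validation on the training set.
#' @param models classifier families to evaluate: subset of
#'   `"logistic"`, `"knn"`, `"tree"`, `"forest"`.
#' @param seed master seed; repetition r uses a derived child seed.
#' @param stratified stratify splits and folds by group label.
#' @param k_videos how many top-ranked videos feed the feature table.
#' @param feature_type `"mean_position"` (average viewing position per
#'   selected video; default) or `"signed_dispersion"` (diagnostic, see
#'   [build_dispersion_features()]).
#' @param frames_mode `"all"` evaluable frames (default) or
#'   `"significant"`: restrict features to frames significant in the
#'   selection analysis (exploratory).
#' @return list of class `eval_protocol`.
#' @export
eval_protocol <- function(train_fraction = 0.8, n_repetitions = 18,
                          cv_folds = 5,
                          models = c("logistic", "knn", "tree", "forest"),
                          seed = 1, stratified = TRUE, k_videos = 2,
                          feature_type = c("mean_position",
                                           "signed_dispersion"),
                          frames_mode = c("all", "significant")) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  assert_that(n_repetitions >= 1, "need at least one repetition")
  assert_that(cv_folds >= 2, "need at least 2 folds")
  unknown <- setdiff(models, c("logistic", "knn", "tree", "forest"))
  assert_that(length(unknown) == 0,
              sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
  structure(list(train_fraction = train_fraction,
                 n_repetitions = n_repetitions, cv_folds = cv_folds,
                 models = models, seed = seed, stratified = stratified,
                 k_videos = k_videos,
                 feature_type = match.arg(feature_type),
                 frames_mode = match.arg(frames_mode)),
            class = "eval_protocol")
}

#' Pinned classifier hyperparameters
#'
#' The evaluation does no hyperparameter search; each family runs with one
#' fixed, documented setting: logistic regression (binomial GLM, 0.5
#' threshold), k-nearest neighbours (k = 5 on training-standardised
#' features), decision tree (rpart, cp = 0.01, minsplit = 20), random
#' forest (500 trees, mtry = floor(sqrt(p))).
#'
#' @return named list of per-model parameter lists.
#' @export
classifier_defaults <- function() {
  list(logistic = list(threshold = 0.5),
       knn = list(k = 5, standardise = TRUE),
       tree = list(cp = 0.01, minsplit = 20),
       forest = list(ntree = 500))
}

#' Stratified train/test split of participants
#'
#' Per class, `floor(train_fraction * n_class)` participants are drawn for
#' training; classes are then topped up in order of largest fractional
#' remainder until the training set has `floor(train_fraction * N)`
#' members. Deterministic given (protocol seed, repetition).
#'
#' @param participants participant ids.
#' @param groups a `group_assignment` covering them.
#' @param protocol an [eval_protocol()].
#' @param repetition repetition index (1-based).
#' @return list with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_participants <- function(participants, groups, protocol, repetition) {
  lab <- group_labels(groups, participants)
  assert_that(all(table(lab) >= 2), "need >= 2 participants per class")
  n_total <- length(participants)
  target <- floor(protocol$train_fraction * n_total)
  withr::with_seed(derive_seed(protocol$seed, 1000 + repetition), {
    if (protocol$stratified) {
      classes <- sort(unique(lab))
      quota <- floor(protocol$train_fraction * table(lab)[classes])
      remainder <- protocol$train_fraction * table(lab)[classes] - quota
      short <- target - sum(quota)
      if (short > 0) {
        bump <- order(-remainder)[seq_len(short)]
        quota[bump] <- quota[bump] + 1
      }
      train <- unlist(lapply(classes, function(cl) {
        ids <- participants[lab == cl]
        sample(ids, quota[[cl]])
      }), use.names = FALSE)
    } else {
      train <- sample(participants, target)
    }
  })
  test <- setdiff(participants, train)
  if (!all(c("low", "high") %in% lab[train])) {
    stop_gd("a class is absent from the training set")
  }
  list(train = sort(train), test = sort(test))
}

# Stratified fold assignment: within each class, shuffled round-robin.
make_folds <- function(labels, n_folds, stratified = TRUE) {
  n <- length(labels)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  } else {
    folds <- sample(rep_len(seq_len(n_folds), n))
  }
  folds
}

feature_matrix <- function(features) {
  as.matrix(features[setdiff(names(features), "participant_id")])
}

# Fit one classifier family; returns an object predict_model() understands.
fit_model <- function(model, X, y, params = classifier_defaults()) {
  y <- factor(y, levels = c("low", "high"))
  fit <- switch(
    model,
    logistic = {
      df <- data.frame(.y = y, X)
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    },
    knn = {
      p <- params$knn
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1
      list(train = scale(X, mu, sdv), cl = y, k = p$k, mu = mu, sd = sdv)
    },
    tree = {
      p <- params$tree
      df <- data.frame(.y = y, X)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = p$cp,
                                                  minsplit = p$minsplit))
    },
    forest = {
      randomForest::randomForest(X, y, ntree = params$forest$ntree)
    },
    stop_gd(sprintf("unknown model token: %s", model)))
  structure(list(model = model, fit = fit, params = params),
            class = "gazediff_model")
}

predict_model <- function(object, X) {
  fit <- object$fit
  switch(
    object$model,
    logistic = {
      p <- stats::predict(fit, newdata = data.frame(X), type = "response")
      factor(ifelse(p > object$params$logistic$threshold, "high", "low"),
             levels = c("low", "high"))
    },
    knn = {
      class::knn(fit$train, scale(X, fit$mu, fit$sd), fit$cl, k = fit$k)
    },
    tree = stats::predict(fit, newdata = data.frame(X), type = "class"),
    forest = stats::predict(fit, newdata = X))
}

#' Cross-validated accuracy of one classifier on training participants
#'
#' Runs stratified `cv_folds`-fold cross-validation over the training rows,
#' then refits the model on the full training set.
#'
#' @param features a `feature_table` for the training participants.
#' @param groups a `group_assignment`.
#' @param protocol an [eval_protocol()].
#' @param model one of `"logistic"`, `"knn"`, `"tree"`, `"forest"`.
#' @return list with `cv_accuracy` (mean over folds) and `fit` (the model
#'   refit on all training rows).
#' @export
fit_and_score <- function(features, groups, protocol, model) {
  X <- feature_matrix(features)
  y <- group_labels(groups, features$participant_id)
  folds <- make_folds(y, protocol$cv_folds, protocol$stratified)
  acc <- vapply(seq_len(protocol$cv_folds), function(f) {
    tr <- folds != f
    fit <- fit_model(model, X[tr, , drop = FALSE], y[tr])
    pred <- predict_model(fit, X[!tr, , drop = FALSE])
    mean(as.character(pred) == y[!tr])
  }, 0)
  list(cv_accuracy = mean(acc),
       fit = fit_model(model, X, y))
}

#' Accuracy of a fitted model on held-out participants
#'
#' @param fit a fitted model from [fit_and_score()].
#' @param features `feature_table` for the test participants (built with
#'   training-derived selection and imputation only).
#' @param groups a `group_assignment`.
#' @return test accuracy in `[0, 1]`.
#' @export
evaluate_holdout <- function(fit, features, groups) {
  assert_that(nrow(features) > 0, "empty test set")
  y <- group_labels(groups, features$participant_id)
  pred <- predict_model(fit, feature_matrix(features))
  mean(as.character(pred) == y)
}

#' Repeated 80/20 holdout evaluation of the full pipeline
#'
#' For each repetition: split participants; run the frame-wise analysis on
#' TRAINING participants only; rank videos and select the top k; build
#' average-viewing-position features (test rows transformed with
#' training-fit imputation); fit each classifier with cross-validation on
#' training; score held-out accuracy. Rankings carry provenance tokens and
#' the selection step rejects full-cohort rankings, so test participants
#' cannot leak into selection.
#'
#' @param matrices named list of `frame_gaze_matrix` for the whole cohort.
#' @param groups a `group_assignment` for all participants.
#' @param protocol an [eval_protocol()].
#' @param cfg an [analysis_config()].
#' @param demonstrate_leakage if `TRUE`, deliberately VIOLATES the protocol
#'   by computing video selection (and, for the signed-dispersion features,
#'   the reference statistics) on the full cohort including test
#'   participants. Only for demonstrating how leakage inflates accuracy;
#'   the report is flagged `leaky`.
#' @return list of class `evaluation_report`: `results` (one row per
#'   repetition x model: cv_accuracy, test_accuracy), `summary` (per-model
#'   means and sds), `repetitions` (split membership and selected videos),
#'   `protocol`, `leaky`.
#' @export
repeated_protocol <- function(matrices, groups, protocol = eval_protocol(),
                              cfg = analysis_config(),
                              demonstrate_leakage = FALSE) {
  participants <- sort(Reduce(intersect, lapply(matrices, `[[`, "participants")))
  assert_that(length(participants) >= 5, "too few participants")
  rows <- list()
  reps <- list()
  for (r in seq_len(protocol$n_repetitions)) {
    sp <- split_participants(participants, groups, protocol, r)
    sel_ids <- if (demonstrate_leakage) participants else sp$train
    sel_matrices <- lapply(matrices, subset_participants, participants = sel_ids)
    fw <- cohort_framewise(sel_matrices, groups, cfg)
    prov <- if (demonstrate_leakage) full_cohort_provenance()
            else sprintf("train:rep%d", r)
    ranking <- rank_videos(fw$summaries, prov)
    selected <- select_top_k(ranking, protocol$k_videos,
                             require_training = !demonstrate_leakage)

    frames <- NULL
    if (protocol$frames_mode == "significant") {
      frames <- lapply(fw$per_video[selected], function(v) {
        v$frame_stats$frame[v$frame_stats$significant]
      })
    }
    if (protocol$feature_type == "mean_position") {
      ft_train <- build_features(matrices, selected, sp$train, frames = frames)
      ft_test <- build_features(matrices, selected, sp$test, frames = frames,
                                impute_stats = attr(ft_train, "column_means"))
    } else {
      ft_train <- build_dispersion_features(matrices, selected, sp$train,
                                            fw$per_video, sel_ids)
      ft_test <- build_dispersion_features(matrices, selected, sp$test,
                                           fw$per_video, sel_ids)
    }

    withr::with_seed(derive_seed(protocol$seed, 2000 + r), {
      for (model in protocol$models) {
        scored <- fit_and_score(ft_train, groups, protocol, model)
        test_acc <- evaluate_holdout(scored$fit, ft_test, groups)
        rows[[length(rows) + 1L]] <-
          data.frame(repetition = r, model = model,
                     cv_accuracy = scored$cv_accuracy,
                     test_accuracy = test_acc,
                     stringsAsFactors = FALSE)
      }
    })
    reps[[r]] <- list(train = sp$train, test = sp$test, selected = selected)
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$model), function(d) {
    data.frame(model = d$model[1],
               mean_cv_accuracy = mean(d$cv_accuracy),
               sd_cv_accuracy = stats::sd(d$cv_accuracy),
               mean_test_accuracy = mean(d$test_accuracy),
               sd_test_accuracy = stats::sd(d$test_accuracy),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, repetitions = reps,
                 protocol = protocol, leaky = demonstrate_leakage),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d repetitions%s\n",
              x$protocol$n_repetitions,
              if (isTRUE(x$leaky)) " [LEAKY DEMONSTRATION]" else ""))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    protocol = unclass(report$protocol),
    leaky = report$leaky,
    summary = report$summary,
    results = report$results,
    repetitions = lapply(report$repetitions, function(r) {
      list(train = r$train, test = r$test, selected = r$selected)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
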