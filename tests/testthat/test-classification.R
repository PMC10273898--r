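make_groups <- function(ids, labels) {
  structure(data.frame(participant_id = ids, label = labels,
                       stringsAsFactors = FALSE),
            class = c("group_assignment", "data.frame"))
}

test_that("stratified splits are disjoint, exhaustive, sized and reproducible", {
  ids <- sprintf("p%02d", 1:10)
  g <- make_groups(ids, rep(c("low", "high"), each = 5))
  pr <- eval_protocol(seed = 3)
  sp <- split_participants(ids, g, pr, 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), ids)
  lab <- group_labels(g, sp$train)
  expect_equal(as.vector(table(lab)), c(4L, 4L))

  expect_identical(split_participants(ids, g, pr, 1), sp)
  expect_false(identical(split_participants(ids, g, pr, 2), sp))

  # 98 participants at 45/53: train floor(0.8 * 98) = 78, test 20
  ids98 <- sprintf("q%03d", 1:98)
  g98 <- make_groups(ids98, rep(c("low", "high"), c(53, 45)))
  sp98 <- split_participants(ids98, g98, pr, 1)
  expect_length(sp98$train, 78)
  expect_length(sp98$test, 20)
  lab98 <- group_labels(g98, sp98$train)
  expect_equal(sum(lab98 == "low"), 42)   # floor(0.8 * 53), no top-up needed
  expect_equal(sum(lab98 == "high"), 36)  # floor(0.8 * 45)
})

well_separated_features <- function(n_per_class = 20, sd = 10, seed = 5) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(2 * n_per_class))
  labels <- rep(c("low", "high"), each = n_per_class)
  centres <- ifelse(labels == "low", 0, 1)
  ft <- data.frame(
    participant_id = ids,
    f_x = rnorm(2 * n_per_class, 100 + 900 * centres, sd),
    f_y = rnorm(2 * n_per_class, 100 + 700 * centres, sd),
    stringsAsFactors = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  list(features = ft, groups = make_groups(ids, labels))
}

test_that("every classifier separates two well-separated point clouds", {
  d <- well_separated_features()
  pr <- eval_protocol(seed = 6)
  set.seed(1)
  for (model in c("logistic", "knn", "tree", "forest")) {
    res <- fit_and_score(d$features, d$groups, pr, model)
    expect_gte(res$cv_accuracy, 0.95)
    expect_equal(evaluate_holdout(res$fit, d$features, d$groups), 1)
  }
  expect_error(fit_and_score(d$features, d$groups, pr, "svm"),
               "unknown model")
})

test_that("shuffled labels on null features sit at chance", {
  set.seed(7)
  ids <- sprintf("p%02d", 1:40)
  ft <- data.frame(participant_id = ids,
                   f_x = rnorm(40), f_y = rnorm(40))
  class(ft) <- c("feature_table", "data.frame")
  accs <- replicate(10, {
    g <- make_groups(ids, sample(rep(c("low", "high"), 20)))
    fit_and_score(ft, g, eval_protocol(seed = 8), "logistic")$cv_accuracy
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("duplicating feature columns barely moves logistic accuracy", {
  d <- well_separated_features(sd = 200, seed = 9)  # overlapping clouds
  pr <- eval_protocol(seed = 10)
  set.seed(2)
  base <- fit_and_score(d$features, d$groups, pr, "logistic")
  dup <- d$features
  dup$f_x2 <- dup$f_x
  dup$f_y2 <- dup$f_y
  class(dup) <- c("feature_table", "data.frame")
  set.seed(2)
  dup_fit <- fit_and_score(dup, d$groups, pr, "logistic")
  expect_lt(abs(base$cv_accuracy - dup_fit$cv_accuracy), 0.11)
})

test_that("holdout evaluation is plain accuracy and rejects empty test sets", {
  d <- well_separated_features()
  pr <- eval_protocol(seed = 11)
  set.seed(3)
  res <- fit_and_score(d$features, d$groups, pr, "tree")
  expect_error(evaluate_holdout(res$fit, d$features[0, ], d$groups),
               "empty test set")
  one_each <- d$features[c(1, 21), ]
  acc <- evaluate_holdout(res$fit, one_each, d$groups)
  expect_true(acc %in% c(0, 0.5, 1))
})

test_that("the repeated protocol recovers a planted location signal and is reproducible", {
  co <- small_cohort(seed = 41, offset_px = 45, dispersion_ratio = 1.5)
  mats <- build_frame_matrices(co$gaze, co$config$fps)
  g <- cohort_groups(co)
  pr <- eval_protocol(seed = 12, n_repetitions = 4, models = "logistic")
  rep1 <- repeated_protocol(mats, g, pr)
  expect_gt(rep1$summary$mean_test_accuracy, 0.7)
  expect_equal(nrow(rep1$results), 4)
  expect_true(all(rep1$results$cv_accuracy >= 0 &
                    rep1$results$cv_accuracy <= 1))
  for (r in rep1$repetitions) {
    expect_length(intersect(r$train, r$test), 0)
    expect_setequal(c(r$train, r$test), mats[[1]]$participants)
  }
  # same protocol, same seed: identical report
  rep2 <- repeated_protocol(mats, g, pr)
  expect_identical(rep1$results, rep2$results)

  # n_repetitions = 1 is a single pass
  pr1 <- eval_protocol(seed = 13, n_repetitions = 1, models = "logistic")
  expect_equal(nrow(repeated_protocol(mats, g, pr1)$results), 1)
})

test_that("on a null cohort the protocol stays at chance while a leaky variant inflates", {
  co <- generate_null_cohort(small_sim_config(seed = 51, n_participants = 40,
                                              group_sizes = c(low = 20, high = 20),
                                              duration_s = 10))
  mats <- build_frame_matrices(co$gaze, co$config$fps)
  g <- cohort_groups(co)
  pr <- eval_protocol(seed = 14, n_repetitions = 6, models = "logistic",
                      feature_type = "signed_dispersion", k_videos = 3)
  proper <- repeated_protocol(mats, g, pr)
  leaky <- repeated_protocol(mats, g, pr, demonstrate_leakage = TRUE)
  expect_true(leaky$leaky)
  expect_gt(leaky$summary$mean_test_accuracy,
            proper$summary$mean_test_accuracy)
  expect_lt(proper$summary$mean_test_accuracy, 0.72)
})
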