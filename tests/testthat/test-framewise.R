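test_that("group centre and distances match brute force", {
  expect_equal(group_centre(c(0, 10), c(0, 0)), c(x = 5, y = 0))
  expect_equal(group_centre(3, 4), c(x = 3, y = 4))
  expect_error(group_centre(NA_real_, NA_real_), "undefined")

  expect_equal(distances_to_centre(3, 4, c(0, 0)), 5)
  expect_equal(distances_to_centre(7, 7, c(7, 7)), 0)

  set.seed(10)
  for (i in 1:20) {
    x <- runif(6, 0, 1280); y <- runif(6, 0, 900)
    x[sample(6, 1)] <- NA; y[is.na(x)] <- NA
    ctr <- group_centre(x, y)
    expect_equal(unname(ctr), oracle_mean2d(x, y), tolerance = 1e-12)
    d <- distances_to_centre(x, y, ctr)
    expect_equal(d[!is.na(d)], oracle_dist(x, y, ctr)[!is.na(x)],
                 tolerance = 1e-12)
  }
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  r <- frame_ttest(c(1, 2, 3), c(4, 5, 6))
  o <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, o$t, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
  expect_equal(r$df, 4)

  same <- frame_ttest(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  a <- c(1.2, 5.3, 2.2, 8); b <- c(4.4, 0.1, 9)
  expect_equal(frame_ttest(a, b)$t_stat, -frame_ttest(b, a)$t_stat)
  expect_equal(frame_ttest(a, b)$p_value, frame_ttest(b, a)$p_value)

  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    r <- frame_ttest(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance frames follow the stated conventions", {
  r <- frame_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  r2 <- frame_ttest(c(1, 1, 1), c(2, 2, 2))
  expect_true(r2$significant)
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 0)
})

test_that("video_framewise matches a per-frame scalar recomputation", {
  co <- small_cohort(seed = 21)
  m <- build_frame_matrices(co$gaze, co$config$fps)[[1]]
  g <- cohort_groups(co)
  cfg <- analysis_config()
  res <- video_framewise(m, g, cfg)
  fs <- res$frame_stats
  lab <- group_labels(g, m$participants)
  for (f in sample(which(fs$evaluable), 25)) {
    dl <- dh <- NULL
    for (grp in c("low", "high")) {
      ids <- m$participants[lab == grp]
      ctr <- group_centre(m$x[f, ids], m$y[f, ids])
      d <- distances_to_centre(m$x[f, ids], m$y[f, ids], ctr)
      if (grp == "low") dl <- d[!is.na(d)] else dh <- d[!is.na(d)]
    }
    ref <- frame_ttest(dl, dh, cfg$alpha)
    expect_equal(fs$t_stat[f], ref$t_stat, tolerance = 1e-10)
    expect_equal(fs$p_value[f], ref$p_value, tolerance = 1e-10)
  }
})

test_that("participants glued to one shared point per group give 0% significant", {
  n <- 10
  x <- matrix(rep(c(rep(200, 5), rep(200, 5)), each = 50), 50, n)
  y <- matrix(300, 50, n)
  colnames(x) <- colnames(y) <- sprintf("p%02d", 1:n)
  m <- frame_gaze_matrix("v", 30, x, y)
  g <- structure(data.frame(participant_id = colnames(x),
                            label = rep(c("low", "high"), each = 5)),
                 class = c("group_assignment", "data.frame"))
  res <- video_framewise(m, g, analysis_config())
  expect_equal(res$summary$pct_significant, 0)
  expect_true(all(res$frame_stats$degenerate))
})

test_that("planted high-dispersion frames are where significance concentrates", {
  set.seed(33)
  n_frames <- 300; n <- 50
  sd_mat <- matrix(20, n_frames, n)
  sd_mat[101:200, 26:50] <- 60  # frames 100-199 (0-indexed), high group
  x <- matrix(rnorm(n_frames * n, 640, sd_mat), n_frames, n)
  y <- matrix(rnorm(n_frames * n, 450, sd_mat), n_frames, n)
  colnames(x) <- colnames(y) <- sprintf("p%02d", 1:n)
  m <- frame_gaze_matrix("v", 30, x, y)
  g <- structure(data.frame(participant_id = colnames(x),
                            label = rep(c("low", "high"), each = 25)),
                 class = c("group_assignment", "data.frame"))
  fs <- video_framewise(m, g, analysis_config())$frame_stats
  inside <- fs$significant[fs$frame %in% 100:199]
  outside <- fs$significant[!fs$frame %in% 100:199]
  expect_gt(mean(inside), 0.8)
  expect_lt(mean(outside), 0.2)
})

test_that("percent significant is invariant to translation and rescaling", {
  co <- small_cohort(seed = 22)
  m <- build_frame_matrices(co$gaze, co$config$fps)[[2]]
  g <- cohort_groups(co)
  base <- video_framewise(m, g)

  shifted <- frame_gaze_matrix(m$video_id, m$fps, m$x + 137, m$y - 55)
  scaled <- frame_gaze_matrix(m$video_id, m$fps, m$x * 2.5, m$y * 2.5)
  expect_equal(video_framewise(shifted, g)$frame_stats$t_stat,
               base$frame_stats$t_stat, tolerance = 1e-9)
  expect_equal(video_framewise(scaled, g)$summary$pct_significant,
               base$summary$pct_significant)
})

test_that("frames below min_per_group are excluded from the denominator", {
  co <- small_cohort(seed = 23)
  m <- build_frame_matrices(co$gaze, co$config$fps)[[1]]
  g <- cohort_groups(co)
  low_ids <- g$participant_id[g$label == "low"]
  # blank out all but two low-group participants on the first 10 frames
  m$x[1:10, intersect(m$participants, low_ids[-(1:2)])] <- NA
  m$y[1:10, intersect(m$participants, low_ids[-(1:2)])] <- NA
  res <- video_framewise(m, g, analysis_config(min_per_group = 3))
  expect_true(all(!res$frame_stats$evaluable[1:10]))
  expect_equal(res$summary$n_evaluable_frames, m$n_frames - 10)
  expect_equal(res$summary$pct_significant,
               100 * sum(res$frame_stats$significant) /
                 (m$n_frames - 10))
})

test_that("category summaries give per-category mean and SEM over videos", {
  s <- data.frame(video_id = paste0("v", 1:8),
                  category = rep(c("A", "B"), each = 4),
                  pct_significant = c(10, 10, 10, 10, 4, 6, 8, 10))
  cs <- category_summary(s)
  expect_equal(cs$mean_pct[cs$category == "A"], 10)
  expect_equal(cs$sem[cs$category == "A"], 0)
  expect_equal(cs$mean_pct[cs$category == "B"], 7)
  expect_equal(cs$sem[cs$category == "B"], sd(c(4, 6, 8, 10)) / 2,
               tolerance = 1e-12)
  # permuting video order changes nothing
  expect_equal(category_summary(s[sample(8), ]), cs)
  expect_warning(category_summary(
    data.frame(video_id = "v", category = "solo", pct_significant = 5)),
    "SEM undefined")
})

test_that("category ANOVA has the right structure and matches brute force", {
  set.seed(44)
  s <- data.frame(video_id = sprintf("v%02d", 1:16),
                  category = rep(c("FUN", "SPORT", "PRODUCT", "CONTROL"),
                                 each = 4),
                  pct_significant = runif(16, 3, 15))
  a <- category_anova(s)
  expect_equal(a$df_between, 3)
  expect_equal(a$df_within, 12)
  o <- oracle_anova(s$pct_significant, s$category)
  expect_equal(a$f_stat, o$f, tolerance = 1e-10)
  expect_equal(a$p_value, o$p, tolerance = 1e-10)
  expect_equal(a$eta_squared, o$eta2, tolerance = 1e-10)

  # equal within categories, different across: eta squared = 1
  s2 <- s; s2$pct_significant <- rep(c(4, 8, 12, 16), each = 4)
  expect_equal(suppressWarnings(category_anova(s2))$eta_squared, 1)

  s3 <- s; s3$pct_significant <- 5
  expect_error(category_anova(s3), "zero total variance")
})
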