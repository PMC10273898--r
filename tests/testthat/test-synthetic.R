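test_that("target trajectories stay in bounds and honour the step scale", {
  tr <- generate_target_trajectory(1, seed = 1)
  expect_equal(dim(tr), c(1, 2))
  for (s in 1:10) {
    tr <- generate_target_trajectory(5000, seed = s, step_px = 12)
    expect_true(all(tr[, "x"] >= 0 & tr[, "x"] <= 1280))
    expect_true(all(tr[, "y"] >= 0 & tr[, "y"] <= 900))
  }
  # away from the edges reflection is rare, so the empirical step SD should
  # track the configured scale
  big <- screen_dims(20000, 20000)
  tr <- generate_target_trajectory(10000, screen = big, seed = 2, step_px = 12)
  expect_lt(abs(sd(diff(tr[, "x"])) - 12) / 12, 0.05)
  expect_lt(abs(sd(diff(tr[, "y"])) - 12) / 12, 0.05)
  # determinism
  expect_identical(generate_target_trajectory(100, seed = 7),
                   generate_target_trajectory(100, seed = 7))
})

test_that("cohort generation is deterministic and respects blink settings", {
  co1 <- small_cohort(seed = 61)
  co2 <- small_cohort(seed = 61)
  expect_identical(co1$gaze, co2$gaze)
  expect_identical(co1$gacs, co2$gacs)

  co0 <- small_cohort(seed = 62, blink_rate = 0)
  expect_true(all(co0$gaze$valid))
  mats <- build_frame_matrices(co0$gaze, co0$config$fps)
  expect_false(any(vapply(mats, function(m) anyNA(m$x), TRUE)))

  cob <- small_cohort(seed = 62, blink_rate = 0.3)
  expect_lt(abs(mean(!cob$gaze$valid) - 0.3), 0.01)
  expect_true(all(is.na(cob$gaze$x_px[!cob$gaze$valid])))
})

test_that("generated noise matches the configured within-group SD", {
  co <- small_cohort(seed = 63, blink_rate = 0, n_videos = 1,
                     duration_s = 20, sigma_base_px = 60,
                     dispersion_ratio = 1)
  # compare valid samples against the known target trajectory
  cfg <- co$config
  traj <- generate_target_trajectory(cfg$duration_s * cfg$fps, cfg$screen,
                                     seed = derive_seed(cfg$seed, 10, 1),
                                     step_px = cfg$walk_step_px)
  g <- co$gaze
  frame <- floor(g$t_ms / 1000 * cfg$fps + 1e-9) + 1
  resid <- g$x_px - traj[frame, "x"]
  # clamping at screen edges truncates a small tail; keep interior frames
  interior <- traj[frame, "x"] > 200 & traj[frame, "x"] < 1080
  expect_lt(abs(sd(resid[interior]) - 60) / 60, 0.05)
})

test_that("null cohorts carry no signal and look null to the pipeline", {
  co <- generate_null_cohort(small_sim_config(seed = 64))
  expect_length(co$truth$signal_videos, 0)
  expect_true(all(!vapply(co$truth$videos, `[[`, TRUE, "signal")))

  mats <- build_frame_matrices(co$gaze, co$config$fps)
  fw <- cohort_framewise(mats, true_group_assignment(co), analysis_config())
  # chance-level ballpark at this size; the tight calibration claim is
  # exercised at full scale in the acceptance suite
  expect_lt(mean(fw$summaries$pct_significant), 12)
})

test_that("GACS synthesis lets the median split recover the latent groups", {
  agree <- vapply(1:5, function(s) {
    co <- generate_cohort(sim_config(seed = 500 + s, n_videos = 1,
                                     duration_s = 1))
    g <- median_split(score_gacs_table(co$gacs))
    mean(group_labels(g, names(co$truth$group)) == co$truth$group)
  }, 0)
  expect_gte(mean(agree), 0.95)
  expect_true(all(vapply(1:3, function(s) {
    co <- generate_cohort(sim_config(seed = 600 + s, n_videos = 1,
                                     duration_s = 1))
    all(score_gacs_table(co$gacs)$total >= 9 &
          score_gacs_table(co$gacs)$total <= 63)
  }, TRUE)))
})

test_that("increasing the dispersion ratio increases detected signal", {
  mean_pct_signal <- vapply(c(1, 1.5, 2.5), function(ratio) {
    pcts <- vapply(1:4, function(s) {
      co <- small_cohort(seed = 700 + s, dispersion_ratio = ratio,
                         n_participants = 40,
                         group_sizes = c(low = 20, high = 20),
                         duration_s = 10, n_videos = 2,
                         signal_videos = "video01")
      mats <- build_frame_matrices(co$gaze, co$config$fps)
      fw <- cohort_framewise(mats, true_group_assignment(co),
                             analysis_config())
      fw$summaries$pct_significant[fw$summaries$video_id == "video01"]
    }, 0)
    mean(pcts)
  }, 0)
  expect_true(all(diff(mean_pct_signal) > 0))
})

test_that("a cohort written to disk reads back into the same pipeline inputs", {
  co <- small_cohort(seed = 65)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("gaze.csv", "gacs.csv", "manifest.csv", "truth.json"))
  gz <- data.table::fread(file.path(dir, "gaze.csv"), na.strings = "")
  expect_equal(nrow(gz), nrow(co$gaze))
  back <- build_frame_matrices(as.data.frame(gz), co$config$fps)
  orig <- build_frame_matrices(co$gaze, co$config$fps)
  expect_equal(back[[1]]$x, orig[[1]]$x, tolerance = 1e-9)
})
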