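#' Configuration of a synthetic gaze cohort
#'
#' The generator emulates the structure of a two-group dynamic-stimulus
#' eye-tracking study: each video has a latent point of interest moving
#' smoothly across the screen; every participant's gaze tracks it with
#' isotropic Gaussian noise; on designated "signal" frames of designated
#' videos the high-craving group's noise SD is inflated by
#' `dispersion_ratio` and/or its mean gaze shifted by `offset_px`; blinks
#' are i.i.d. per-sample missingness; GACS item responses are drawn with
#' group-shifted means so a median split recovers the latent groups.
#'
#' @param n_participants cohort size (default 98).
#' @param group_sizes named or ordered pair `(low, high)` (default 53, 45).
#' @param n_videos number of videos (default 16, four per category).
#' @param categories advert categories cycled over videos.
#' @param duration_s video duration in seconds (default 30).
#' @param fps video frame rate (default 30).
#' @param sampling_rate_hz tracker sampling rate (default 60).
#' @param screen screen bounds, see [screen_dims()].
#' @param sigma_base_px within-group gaze noise SD in pixels (default 60).
#' @param dispersion_ratio high-group/low-group noise SD on signal frames
#'   (default 1.5; 1 = no dispersion signal).
#' @param offset_px horizontal shift of the high group's mean gaze on
#'   signal frames (default 0; a location signal makes group membership
#'   predictable from average viewing position).
#' @param signal_videos video ids carrying the signal (default the first
#'   two FUN videos); ignored when the signal parameters are null.
#' @param signal_frame_fraction fraction of each signal video's frames that
#'   carry the signal, as one contiguous block (default 0.5).
#' @param blink_rate per-sample probability of a blink/track-loss sample
#'   (default 0.05).
#' @param gacs_p item-response parameters per group: each item is
#'   `1 + Binomial(6, p)`, bounded in 1..7 by construction.
#' @param walk_step_px per-frame SD of the target trajectory's random walk.
#' @param seed master seed for the cohort.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 98,
                       group_sizes = c(low = 53, high = 45),
                       n_videos = 16,
                       categories = c("FUN", "SPORT", "PRODUCT", "CONTROL"),
                       duration_s = 30, fps = 30, sampling_rate_hz = 60,
                       screen = screen_dims(),
                       sigma_base_px = 60, dispersion_ratio = 1.5,
                       offset_px = 0,
                       signal_videos = NULL,
                       signal_frame_fraction = 0.5,
                       blink_rate = 0.05,
                       gacs_p = c(low = 0.06, high = 0.28),
                       walk_step_px = 12,
                       seed = 1) {
  assert_that(sum(group_sizes) == n_participants,
              "group sizes must sum to n_participants")
  assert_that(dispersion_ratio > 0, "dispersion_ratio must be positive")
  assert_that(blink_rate >= 0 && blink_rate < 1, "blink_rate must be in [0,1)")
  assert_that(signal_frame_fraction >= 0 && signal_frame_fraction <= 1,
              "signal_frame_fraction must be in [0,1]")
  video_ids <- sprintf("video%02d", seq_len(n_videos))
  category <- rep_len(rep(categories, each = max(1, n_videos %/% length(categories))),
                      n_videos)
  if (is.null(signal_videos)) {
    signal_videos <- utils::head(video_ids[category == categories[1]], 2)
  }
  assert_that(all(signal_videos %in% video_ids),
              "signal_videos must be among the cohort's videos")
  structure(list(n_participants = n_participants, group_sizes = group_sizes,
                 n_videos = n_videos, video_ids = video_ids,
                 category = category, duration_s = duration_s, fps = fps,
                 sampling_rate_hz = sampling_rate_hz, screen = screen,
                 sigma_base_px = sigma_base_px,
                 dispersion_ratio = dispersion_ratio, offset_px = offset_px,
                 signal_videos = signal_videos,
                 signal_frame_fraction = signal_frame_fraction,
                 blink_rate = blink_rate, gacs_p = gacs_p,
                 walk_step_px = walk_step_px, seed = seed),
            class = "sim_config")
}

#' Smooth bounded target trajectory
#'
#' A Gaussian random walk per axis, reflected at the screen edges, starting
#' at screen centre: a minimal stand-in for the moving point of interest of
#' a dynamic advert. Deterministic given the seed.
#'
#' @param n_frames number of frames.
#' @param screen screen bounds.
#' @param seed RNG seed.
#' @param step_px per-frame step SD in pixels.
#' @return `n_frames x 2` matrix of (x, y) positions within bounds.
#' @export
generate_target_trajectory <- function(n_frames, screen = screen_dims(),
                                       seed = 1, step_px = 12) {
  assert_that(n_frames >= 1, "need at least one frame")
  withr::with_seed(seed, {
    w <- screen[["width"]]; h <- screen[["height"]]
    x <- cumsum(c(w / 2, stats::rnorm(n_frames - 1, 0, step_px)))
    y <- cumsum(c(h / 2, stats::rnorm(n_frames - 1, 0, step_px)))
    cbind(x = reflect_into(x, w), y = reflect_into(y, h))
  })
}

# Fold an unbounded coordinate into [0, limit] by reflection at both edges.
reflect_into <- function(v, limit) {
  v <- v %% (2 * limit)
  ifelse(v > limit, 2 * limit - v, v)
}

#' Generate a synthetic two-group gaze cohort
#'
#' Produces a long gaze-sample table in the package's CSV dialect, matching
#' GACS questionnaire responses, a video manifest, and a ground-truth
#' object recording each participant's latent group and each video's
#' signal frames and group parameters.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with elements `gaze` (data.frame of
#'   samples), `gacs` (questionnaire data.frame), `manifest`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  n_sig_frames <- function(nf) round(cfg$signal_frame_fraction * nf)
  ids <- sprintf("p%03d", seq_len(cfg$n_participants))
  true_group <- rep(c("low", "high"), times = cfg$group_sizes)
  names(true_group) <- ids

  n_frames <- ceiling(cfg$duration_s * cfg$fps)
  n_samples <- round(cfg$duration_s * cfg$sampling_rate_hz)
  t_ms <- (seq_len(n_samples) - 1) / cfg$sampling_rate_hz * 1000
  sample_frame <- time_to_frame(t_ms, cfg$fps) + 1L

  has_signal <- cfg$video_ids %in% cfg$signal_videos &
    (cfg$dispersion_ratio != 1 || cfg$offset_px != 0)

  gaze_parts <- vector("list", cfg$n_videos)
  truth_videos <- list()
  for (v in seq_len(cfg$n_videos)) {
    vid <- cfg$video_ids[v]
    traj <- generate_target_trajectory(n_frames, cfg$screen,
                                       seed = derive_seed(cfg$seed, 10, v),
                                       step_px = cfg$walk_step_px)
    sig_frames <- integer(0)
    if (has_signal[v]) {
      k <- n_sig_frames(n_frames)
      start <- floor(n_frames / 4)
      sig_frames <- seq.int(start, length.out = k) %% n_frames
      sig_frames <- sort(unique(sig_frames))
    }
    signal_sample <- (sample_frame - 1L) %in% sig_frames

    withr::with_seed(derive_seed(cfg$seed, 20, v), {
      n_cells <- cfg$n_participants * n_samples
      part <- rep(ids, each = n_samples)
      grp <- rep(true_group, each = n_samples)
      sd_px <- rep(cfg$sigma_base_px, n_cells)
      mu_shift <- numeric(n_cells)
      is_high <- grp == "high"
      on_sig <- rep(signal_sample, times = cfg$n_participants)
      sd_px[is_high & on_sig] <- cfg$sigma_base_px * cfg$dispersion_ratio
      mu_shift[is_high & on_sig] <- cfg$offset_px

      base_x <- rep(traj[sample_frame, "x"], times = cfg$n_participants)
      base_y <- rep(traj[sample_frame, "y"], times = cfg$n_participants)
      x <- stats::rnorm(n_cells, base_x + mu_shift, sd_px)
      y <- stats::rnorm(n_cells, base_y, sd_px)
      x <- pmin(pmax(x, 0), cfg$screen[["width"]])
      y <- pmin(pmax(y, 0), cfg$screen[["height"]])
      blink <- stats::runif(n_cells) < cfg$blink_rate
      x[blink] <- NA_real_
      y[blink] <- NA_real_

      gaze_parts[[v]] <- data.frame(
        participant_id = part, video_id = vid,
        t_ms = rep(t_ms, times = cfg$n_participants),
        x_px = x, y_px = y, valid = !blink,
        stringsAsFactors = FALSE)
    })
    truth_videos[[vid]] <- list(
      signal = has_signal[v],
      signal_frames = sig_frames,
      sigma_low = cfg$sigma_base_px,
      sigma_high_signal = cfg$sigma_base_px *
        if (has_signal[v]) cfg$dispersion_ratio else 1,
      offset_high_signal = if (has_signal[v]) cfg$offset_px else 0)
  }

  withr::with_seed(derive_seed(cfg$seed, 30), {
    p_item <- cfg$gacs_p[true_group]
    items <- matrix(1L + stats::rbinom(9 * cfg$n_participants, 6,
                                       rep(p_item, each = 9)),
                    ncol = 9, byrow = TRUE,
                    dimnames = list(NULL, paste0("item", 1:9)))
  })
  gacs <- data.frame(participant_id = ids, items, stringsAsFactors = FALSE)

  manifest <- data.frame(video_id = cfg$video_ids, category = cfg$category,
                         duration_s = cfg$duration_s,
                         stringsAsFactors = FALSE)
  truth <- list(group = true_group, videos = truth_videos,
                signal_videos = cfg$video_ids[has_signal])
  structure(list(gaze = do.call(rbind, gaze_parts), gacs = gacs,
                 manifest = manifest, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Generate a null cohort (no gaze group difference)
#'
#' [generate_cohort()] with `dispersion_ratio = 1` and `offset_px = 0`:
#' both groups' gaze comes from one distribution, so any detected
#' difference is type-I error. The truth object marks no signal videos.
#'
#' @param cfg a [sim_config()]; its signal parameters are overridden.
#' @return a `sim_cohort`.
#' @export
generate_null_cohort <- function(cfg = sim_config()) {
  cfg$dispersion_ratio <- 1
  cfg$offset_px <- 0
  generate_cohort(cfg)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d participants (%s), %d videos, %d gaze samples; signal videos: %s\n",
              x$config$n_participants,
              paste(x$config$group_sizes, collapse = "/"),
              x$config$n_videos, nrow(x$gaze),
              if (length(x$truth$signal_videos))
                paste(x$truth$signal_videos, collapse = ", ") else "none"))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits `gaze.csv`, `gacs.csv`, `manifest.csv` and `truth.json`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gz <- cohort$gaze
  gz$valid <- as.integer(gz$valid)
  data.table::fwrite(gz, file.path(dir, "gaze.csv"), na = "", quote = FALSE)
  write_gacs_csv(cohort$gacs, file.path(dir, "gacs.csv"))
  write_video_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
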