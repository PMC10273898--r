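#' Analysis configuration for the frame-wise statistic
#'
#' @param alpha uncorrected per-frame significance level for the Student's
#'   t-test on distances (default 0.05). No multiple-testing correction is
#'   applied by design: per-frame "significance" is only used as a counting
#'   device, never as a frame-level inferential claim.
#' @param min_per_group minimum non-missing participants per group for a
#'   frame to be evaluable (default 3). Frames below it are excluded from
#'   the percentage denominator rather than imputed.
#' @param fps video frame rate used when resampling gaze samples.
#' @param leave_one_out if `TRUE`, each participant's distance is taken to
#'   their group's centre computed without them. Default `FALSE`: the
#'   contributing participant is included in the centre.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, min_per_group = 3, fps = 30,
                            leave_one_out = FALSE) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(min_per_group >= 2, "min_per_group must be >= 2")
  assert_that(fps > 0, "fps must be positive")
  structure(list(alpha = alpha, min_per_group = min_per_group, fps = fps,
                 leave_one_out = leave_one_out),
            class = "analysis_config")
}

#' Group centre of a set of gaze positions
#'
#' The componentwise arithmetic mean of the non-missing positions.
#'
#' @param x,y numeric vectors of coordinates (`NA` = missing participant).
#' @return numeric `c(x, y)`.
#' @export
group_centre <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stop_gd("no non-missing positions: centre undefined")
  c(x = mean(x[keep]), y = mean(y[keep]))
}

#' Euclidean distances from gaze positions to a centre
#'
#' @param x,y coordinate vectors; missing positions yield `NA` distances.
#' @param centre numeric `c(x, y)`.
#' @return numeric vector of pixel distances, order-preserving.
#' @export
distances_to_centre <- function(x, y, centre) {
  sqrt((x - centre[[1]])^2 + (y - centre[[2]])^2)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Two-sided, with `n1 + n2 - 2` degrees of freedom. Degenerate inputs
#' follow fixed conventions: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means is treated as
#' maximally significant (`p = 0`) and flagged `degenerate`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param alpha significance level for the `significant` flag.
#' @return list with `t_stat`, `p_value`, `df`, `significant`, `degenerate`.
#' @export
frame_ttest <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  assert_that(n1 >= 2 && n2 >= 2, "need >= 2 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) {
      return(list(t_stat = 0, p_value = 1, df = df,
                  significant = FALSE, degenerate = TRUE))
    }
    return(list(t_stat = sign(delta) * Inf, p_value = 0, df = df,
                significant = TRUE, degenerate = TRUE))
  }
  t_stat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, p_value = p, df = df,
       significant = p < alpha, degenerate = FALSE)
}

#' Frame-wise group-difference analysis of one video
#'
#' For every frame: the low and high groups' gaze centres are the mean
#' positions of each group's non-missing participants; each participant's
#' divergence is their Euclidean distance to their OWN group's centre; the
#' two groups' distance samples are compared with a two-sided
#' pooled-variance Student's t-test. A frame is evaluable when both groups
#' have at least `min_per_group` non-missing participants; the video is
#' summarised by the percentage of evaluable frames with `p < alpha`.
#'
#' Distances to the opposite group's centre are also computed and returned
#' (when `keep_distances`) but play no part in the test.
#'
#' @param matrix a `frame_gaze_matrix` (see [build_frame_matrices()]).
#' @param groups a `group_assignment` covering the matrix participants.
#' @param cfg an [analysis_config()].
#' @param keep_distances if `TRUE`, attach per-frame distance matrices
#'   (`d_own`, `d_other`, frames x participants) to the result.
#' @return list of class `video_framewise` with elements `frame_stats`
#'   (data.frame: frame, group centres, group sizes, t_stat, p_value,
#'   significant, evaluable, degenerate) and `summary` (data.frame:
#'   video_id, n_frames, n_evaluable_frames, pct_significant).
#' @export
video_framewise <- function(matrix, groups, cfg = analysis_config(),
                            keep_distances = FALSE) {
  lab <- group_labels(groups, matrix$participants)
  low <- names(lab)[lab == "low"]
  high <- names(lab)[lab == "high"]
  assert_that(length(low) >= cfg$min_per_group &&
                length(high) >= cfg$min_per_group,
              "each group needs at least min_per_group members overall")

  stats_own <- framewise_group_stats(matrix, low, high,
                                     leave_one_out = cfg$leave_one_out)
  fs <- framewise_test(stats_own, cfg)
  fs$frame <- seq_len(matrix$n_frames) - 1L

  n_eval <- sum(fs$evaluable)
  n_sig <- sum(fs$significant & fs$evaluable)
  summary <- data.frame(
    video_id = matrix$video_id,
    n_frames = matrix$n_frames,
    n_evaluable_frames = n_eval,
    pct_significant = if (n_eval > 0) 100 * n_sig / n_eval else 0,
    stringsAsFactors = FALSE)
  if (n_eval == 0) {
    warning(sprintf("video %s has no evaluable frames", matrix$video_id),
            call. = FALSE)
  }

  out <- list(video_id = matrix$video_id,
              frame_stats = fs[c("frame", "centre_low_x", "centre_low_y",
                                 "centre_high_x", "centre_high_y",
                                 "n_low", "n_high", "t_stat", "p_value",
                                 "significant", "evaluable", "degenerate")],
              summary = summary)
  if (keep_distances) {
    out$d_own <- stats_own$d_own
    out$d_other <- stats_own$d_other
  }
  structure(out, class = "video_framewise")
}

#' @export
print.video_framewise <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<video_framewise> video %s: %d/%d evaluable frames, %.2f%% significant\n",
              s$video_id, s$n_evaluable_frames, s$n_frames,
              s$pct_significant))
  invisible(x)
}

# Vectorised per-frame group centres and distances for one video.
# Returns per-frame group sizes, centres, distance means/variances, and the
# full distance matrices (own / other group centre) in participant order.
framewise_group_stats <- function(matrix, low, high, leave_one_out = FALSE) {
  per_group <- function(ids) {
    gx <- matrix$x[, ids, drop = FALSE]
    gy <- matrix$y[, ids, drop = FALSE]
    n <- rowSums(!is.na(gx))
    sx <- rowSums(gx, na.rm = TRUE)
    sy <- rowSums(gy, na.rm = TRUE)
    cx <- ifelse(n > 0, sx / n, NA_real_)
    cy <- ifelse(n > 0, sy / n, NA_real_)
    if (leave_one_out) {
      # centre excluding the participant; undefined when alone
      cxi <- (sx - gx) / (n - 1)
      cyi <- (sy - gy) / (n - 1)
      d_own <- sqrt((gx - cxi)^2 + (gy - cyi)^2)
    } else {
      d_own <- sqrt((gx - cx)^2 + (gy - cy)^2)
    }
    list(ids = ids, x = gx, y = gy, n = n, cx = cx, cy = cy, d_own = d_own)
  }
  L <- per_group(low)
  H <- per_group(high)
  d_other_low <- sqrt((L$x - H$cx)^2 + (L$y - H$cy)^2)
  d_other_high <- sqrt((H$x - L$cx)^2 + (H$y - L$cy)^2)

  moments <- function(d, n) {
    m <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / n, NA_real_)
    ss <- rowSums(d^2, na.rm = TRUE) - n * m^2
    v <- ifelse(n > 1, pmax(ss, 0) / (n - 1), NA_real_)
    list(mean = m, var = v)
  }
  ml <- moments(L$d_own, L$n)
  mh <- moments(H$d_own, H$n)

  list(n_low = L$n, n_high = H$n,
       centre_low_x = L$cx, centre_low_y = L$cy,
       centre_high_x = H$cx, centre_high_y = H$cy,
       mean_low = ml$mean, var_low = ml$var,
       mean_high = mh$mean, var_high = mh$var,
       d_own = cbind(L$d_own, H$d_own),
       d_other = cbind(d_other_low, d_other_high))
}

# Vectorised pooled t over frames; matches frame_ttest() conventions.
framewise_test <- function(g, cfg) {
  n1 <- g$n_low; n2 <- g$n_high
  evaluable <- n1 >= cfg$min_per_group & n2 >= cfg$min_per_group
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * g$var_low + (n2 - 1) * g$var_high) / df
  delta <- g$mean_low - g$mean_high
  t_stat <- rep(NA_real_, length(n1))
  p <- rep(NA_real_, length(n1))
  degenerate <- rep(FALSE, length(n1))

  ok <- evaluable & !is.na(sp2) & sp2 > 0
  t_stat[ok] <- delta[ok] / sqrt(sp2[ok] * (1 / n1[ok] + 1 / n2[ok]))
  p[ok] <- 2 * stats::pt(-abs(t_stat[ok]), df[ok])

  deg <- evaluable & !is.na(sp2) & sp2 == 0
  if (any(deg)) {
    eqm <- deg & delta == 0
    t_stat[eqm] <- 0; p[eqm] <- 1
    neq <- deg & delta != 0
    t_stat[neq] <- sign(delta[neq]) * Inf; p[neq] <- 0
    degenerate[deg] <- TRUE
  }
  data.frame(centre_low_x = g$centre_low_x, centre_low_y = g$centre_low_y,
             centre_high_x = g$centre_high_x, centre_high_y = g$centre_high_y,
             n_low = n1, n_high = n2, t_stat = t_stat, p_value = p,
             significant = !is.na(p) & p < cfg$alpha & evaluable,
             evaluable = evaluable, degenerate = degenerate)
}

#' Frame-wise analysis of a whole cohort
#'
#' Runs [video_framewise()] on every video and binds the per-video
#' summaries, attaching advert categories from the manifest when given.
#'
#' @param matrices named list of `frame_gaze_matrix`.
#' @param groups a `group_assignment`.
#' @param cfg an [analysis_config()].
#' @param manifest optional video manifest (adds a `category` column).
#' @return list with `per_video` (list of `video_framewise`) and
#'   `summaries` (one row per video).
#' @export
cohort_framewise <- function(matrices, groups, cfg = analysis_config(),
                             manifest = NULL) {
  per_video <- lapply(matrices, video_framewise, groups = groups, cfg = cfg)
  summaries <- do.call(rbind, lapply(per_video, `[[`, "summary"))
  rownames(summaries) <- NULL
  if (!is.null(manifest)) {
    summaries$category <- manifest$category[
      match(summaries$video_id, manifest$video_id)]
  }
  list(per_video = per_video, summaries = summaries)
}

#' Mean and SEM of percent-significant-frames per advert category
#'
#' The video is the unit of analysis: for each category the mean and
#' standard error of the mean (sd / sqrt(k)) are taken over its k videos.
#'
#' @param summaries data.frame with `video_id`, `category`,
#'   `pct_significant` (as from [cohort_framewise()]).
#' @return data.frame: category, n_videos, mean_pct, sem (NA for
#'   single-video categories, with a warning).
#' @export
category_summary <- function(summaries) {
  assert_that(!is.null(summaries$category), "summaries need a category column")
  cats <- sort(unique(summaries$category))
  out <- do.call(rbind, lapply(cats, function(cat) {
    p <- summaries$pct_significant[summaries$category == cat]
    data.frame(category = cat, n_videos = length(p), mean_pct = mean(p),
               sem = if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (anyNA(out$sem)) {
    warning("SEM undefined for single-video categories", call. = FALSE)
  }
  out
}

#' One-way ANOVA of percent-significant-frames across advert categories
#'
#' Video-level percentages are the observations, category the factor. With
#' 4 categories of 4 videos this gives the (3, 12) degrees-of-freedom
#' structure. Effect size is eta squared = SS_between / SS_total.
#'
#' @param summaries as for [category_summary()].
#' @return data.frame of class `anova_result`: f_stat, df_between,
#'   df_within, p_value, eta_squared.
#' @export
category_anova <- function(summaries) {
  assert_that(!is.null(summaries$category), "summaries need a category column")
  assert_that(length(unique(summaries$category)) >= 2, "need >= 2 categories")
  if (stats::var(summaries$pct_significant) == 0) {
    stop_gd("zero total variance: F undefined")
  }
  fit <- stats::aov(pct_significant ~ factor(category), data = summaries)
  tab <- stats::anova(fit)
  ssb <- tab$`Sum Sq`[1]
  ssw <- tab$`Sum Sq`[2]
  structure(data.frame(f_stat = tab$`F value`[1],
                       df_between = tab$Df[1],
                       df_within = tab$Df[2],
                       p_value = tab$`Pr(>F)`[1],
                       eta_squared = ssb / (ssb + ssw)),
            class = c("anova_result", "data.frame"))
}

#' Write frame-level and video-level statistics as TSV
#'
#' @param result a `video_framewise` or the `summaries` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_framewise_tsv <- function(result, path) {
  tab <- if (inherits(result, "video_framewise")) {
    cbind(video_id = result$video_id,
          result$frame_stats[c("frame", "t_stat", "p_value", "significant",
                               "evaluable")])
  } else {
    result
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
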