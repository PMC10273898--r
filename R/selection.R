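#' Rank videos by group-difference content
#'
#' Videos are ordered by descending percentage of significant frames, ties
#' broken lexicographically by video id so the ranking is deterministic.
#'
#' The `provenance` token records which participants the summaries were
#' computed on. Inside the evaluation protocol selection must be computed on
#' training participants only; a ranking whose provenance is the full cohort
#' is rejected there (see [select_top_k()]).
#'
#' @param summaries data.frame with `video_id` and `pct_significant`.
#' @param provenance token naming the participant subset used, e.g.
#'   `"train:rep1"`, or [full_cohort_provenance()] outside evaluation.
#' @return data.frame of class `video_ranking` (video_id, pct_significant,
#'   rank) with a `provenance` attribute.
#' @export
rank_videos <- function(summaries, provenance) {
  assert_that(nrow(summaries) >= 1, "need at least one video summary")
  assert_that(is.character(provenance) && length(provenance) == 1,
              "provenance must be a single token")
  ord <- order(-summaries$pct_significant, summaries$video_id)
  out <- data.frame(video_id = summaries$video_id[ord],
                    pct_significant = summaries$pct_significant[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  structure(out, provenance = provenance,
            class = c("video_ranking", "data.frame"))
}

#' Provenance token for whole-cohort (non-evaluation) analyses
#' @return the reserved token `"full-cohort"`.
#' @export
full_cohort_provenance <- function() "full-cohort"

#' Take the top-k videos of a ranking
#'
#' @param ranking a `video_ranking`.
#' @param k number of videos, `1 <= k <= nrow(ranking)`.
#' @param require_training if `TRUE` (used inside the evaluation protocol),
#'   a ranking computed on the full cohort raises a protocol-violation
#'   error: selecting videos with test participants' data is leakage.
#' @return character vector of k video ids, in rank order.
#' @export
select_top_k <- function(ranking, k, require_training = FALSE) {
  assert_that(inherits(ranking, "video_ranking"), "need a video_ranking")
  assert_that(k >= 1 && k <= nrow(ranking),
              sprintf("k must be in 1..%d", nrow(ranking)))
  if (require_training &&
      identical(attr(ranking, "provenance"), full_cohort_provenance())) {
    stop_gd(paste("protocol violation: video selection inside the evaluation",
                  "protocol must use a training-only ranking, not the full cohort"))
  }
  ranking$video_id[seq_len(k)]
}

#' Average-viewing-position feature table
#'
#' For each participant and selected video the features are the mean x and
#' mean y gaze position over that video's frames (non-missing cells only) —
#' the participant's average viewing position. A (participant, video) pair
#' with no non-missing frame is imputed with the feature-column mean of the
#' `impute_from` participants and logged.
#'
#' Imputation statistics must come from training participants only when the
#' table is built for held-out participants: pass the training table's
#' `column_means` attribute as `impute_stats`.
#'
#' @param matrices named list of `frame_gaze_matrix` (must cover `selected`).
#' @param selected character vector of selected video ids, in rank order.
#' @param participants participants (matrix columns) to build rows for.
#' @param frames optional named list: for a video id, an integer vector of
#'   0-indexed frames to restrict the average to (default: all frames).
#' @param impute_stats optional named numeric vector of per-column means to
#'   impute with; default: means over the rows being built.
#' @return data.frame of class `feature_table`: `participant_id` plus
#'   `<video>_x`, `<video>_y` columns; attributes `column_means`,
#'   `imputation_log`, `selected_videos`.
#' @export
build_features <- function(matrices, selected, participants,
                           frames = NULL, impute_stats = NULL) {
  assert_that(all(selected %in% names(matrices)),
              "every selected video needs a frame matrix")
  cols <- list()
  for (vid in selected) {
    m <- subset_participants(matrices[[vid]], participants)
    keep <- seq_len(m$n_frames)
    if (!is.null(frames) && !is.null(frames[[vid]])) {
      keep <- frames[[vid]] + 1L
      assert_that(all(keep >= 1 & keep <= m$n_frames),
                  sprintf("frame selection out of range for video %s", vid))
    }
    x <- m$x[keep, , drop = FALSE]
    y <- m$y[keep, , drop = FALSE]
    cols[[paste0(vid, "_x")]] <- colMeans(x, na.rm = TRUE)
    cols[[paste0(vid, "_y")]] <- colMeans(y, na.rm = TRUE)
  }
  ft <- data.frame(participant_id = participants, cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(ft) <- NULL
  feat_cols <- setdiff(names(ft), "participant_id")
  for (cn in feat_cols) ft[[cn]][is.nan(ft[[cn]])] <- NA_real_

  col_means <- vapply(ft[feat_cols], function(v) mean(v, na.rm = TRUE), 0)
  if (is.null(impute_stats)) {
    impute_stats <- col_means
    if (anyNA(impute_stats)) {
      stop_gd("a feature column is fully missing across the reference participants")
    }
  } else {
    assert_that(all(feat_cols %in% names(impute_stats)),
                "impute_stats must cover every feature column")
  }
  log_rows <- list()
  for (cn in feat_cols) {
    miss <- which(is.na(ft[[cn]]))
    if (length(miss)) {
      log_rows[[cn]] <- data.frame(participant_id = ft$participant_id[miss],
                                   column = cn,
                                   imputed_value = impute_stats[[cn]],
                                   stringsAsFactors = FALSE)
      ft[[cn]][miss] <- impute_stats[[cn]]
    }
  }
  imputation_log <- if (length(log_rows)) {
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(participant_id = character(), column = character(),
               imputed_value = numeric())
  }
  structure(ft, column_means = col_means[feat_cols],
            imputation_log = imputation_log,
            selected_videos = selected,
            class = c("feature_table", "data.frame"))
}

#' Signed-dispersion feature table (diagnostic mode)
#'
#' An alternative feature set built from the frame-wise statistic itself,
#' used chiefly to demonstrate selection leakage. For each selected video,
#' a reference [video_framewise()] result supplies the frames with a
#' significant group difference and the sign of each frame's t statistic;
#' the feature is the mean over those frames of
#' `sign(t_f) * distance(participant, pooled centre at frame f)`, where the
#' pooled centre is the mean gaze of the reference participants. When the
#' reference analysis is computed on training participants only this
#' feature carries no information under a null cohort; computed on the full
#' cohort it encodes the (chance) pattern the held-out participants
#' themselves produced — textbook leakage.
#'
#' @param matrices named list of `frame_gaze_matrix`.
#' @param selected selected video ids.
#' @param participants participants to build rows for.
#' @param reference named list of `video_framewise` results (per video)
#'   computed on the reference participant subset.
#' @param reference_participants the participants the reference analysis
#'   used (defines the pooled per-frame centres).
#' @return data.frame of class `feature_table` with one `<video>_disp`
#'   column per selected video.
#' @export
build_dispersion_features <- function(matrices, selected, participants,
                                      reference, reference_participants) {
  cols <- list()
  for (vid in selected) {
    fs <- reference[[vid]]$frame_stats
    sel <- fs$frame[fs$significant]
    m_ref <- subset_participants(matrices[[vid]], reference_participants)
    m <- subset_participants(matrices[[vid]], participants)
    if (length(sel) == 0) {
      cols[[paste0(vid, "_disp")]] <- rep(0, length(participants))
      next
    }
    rows <- sel + 1L
    cx <- rowMeans(m_ref$x[rows, , drop = FALSE], na.rm = TRUE)
    cy <- rowMeans(m_ref$y[rows, , drop = FALSE], na.rm = TRUE)
    s <- sign(fs$t_stat[match(sel, fs$frame)])
    d <- sqrt((m$x[rows, , drop = FALSE] - cx)^2 +
                (m$y[rows, , drop = FALSE] - cy)^2)
    cols[[paste0(vid, "_disp")]] <- colMeans(s * d, na.rm = TRUE)
  }
  ft <- data.frame(participant_id = participants, cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  feat_cols <- setdiff(names(ft), "participant_id")
  for (cn in feat_cols) {
    v <- ft[[cn]]
    v[is.nan(v) | is.na(v)] <- mean(v[!is.nan(v) & !is.na(v)])
    ft[[cn]] <- v
  }
  structure(ft,
            column_means = vapply(ft[feat_cols], mean, 0),
            imputation_log = data.frame(),
            selected_videos = selected,
            class = c("feature_table", "data.frame"))
}

#' Write a feature table as TSV
#' @param features a `feature_table`.
#' @param path output path.
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
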