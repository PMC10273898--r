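#' Screen dimensions helper
#'
#' @param width,height screen size in pixels. Defaults follow a 1280 x 900
#'   video presentation.
#' @return named numeric vector with elements `width` and `height`.
#' @export
screen_dims <- function(width = 1280, height = 900) {
  assert_that(width > 0 && height > 0, "screen dimensions must be positive")
  c(width = width, height = height)
}

#' Construct a single-participant gaze recording
#'
#' A recording holds one participant's timestamped gaze samples for one
#' video. Blinks and track loss are retained as samples with `valid = FALSE`
#' and missing coordinates; they are never imputed at the sample level.
#'
#' @param participant_id,video_id identifier tokens.
#' @param t_ms sample times in milliseconds from video onset (non-negative).
#' @param x_px,y_px gaze coordinates in screen pixels (origin top-left,
#'   y increasing downward); `NA` where `valid` is `FALSE`.
#' @param valid logical; `FALSE` marks blink/track-loss samples.
#' @param sampling_rate_hz nominal tracker sampling rate.
#' @param screen screen bounds, see [screen_dims()].
#' @return an object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, video_id, t_ms, x_px, y_px,
                           valid = rep(TRUE, length(t_ms)),
                           sampling_rate_hz = 60,
                           screen = screen_dims()) {
  assert_that(length(participant_id) == 1 && length(video_id) == 1,
              "participant_id and video_id must be single tokens")
  n <- length(t_ms)
  assert_that(length(x_px) == n && length(y_px) == n && length(valid) == n,
              "t_ms, x_px, y_px, valid must have equal length")
  assert_that(sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  assert_that(all(t_ms >= 0), "sample times must be non-negative")
  valid <- as.logical(valid)
  bad <- which(valid &
                 (is.na(x_px) | is.na(y_px) |
                    x_px < 0 | x_px > screen[["width"]] |
                    y_px < 0 | y_px > screen[["height"]]))
  if (length(bad)) {
    stop_gd(sprintf(
      "valid sample(s) outside screen bounds or missing coordinates (first at sample %d of %s/%s)",
      bad[1], participant_id, video_id))
  }
  ord <- order(t_ms)
  structure(
    list(participant_id = as.character(participant_id),
         video_id = as.character(video_id),
         samples = data.frame(t_ms = t_ms[ord], x_px = x_px[ord],
                              y_px = y_px[ord], valid = valid[ord]),
         sampling_rate_hz = sampling_rate_hz,
         screen = screen),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant %s, video %s: %d samples (%d valid) @ %g Hz\n",
              x$participant_id, x$video_id, nrow(x$samples),
              sum(x$samples$valid), x$sampling_rate_hz))
  invisible(x)
}

#' Read a gaze-sample CSV export
#'
#' Expects the documented dialect: UTF-8, header
#' `participant_id,video_id,t_ms,x_px,y_px,valid`, `valid` coded 0/1, and
#' missing coordinates as empty fields. Rows with `valid = 0` are retained
#' with missing coordinates (the blink convention).
#'
#' @param path path to the CSV file.
#' @param screen screen bounds used to validate coordinates.
#' @return a list of [gaze_recording()] objects, one per
#'   (participant, video) pair, samples sorted by time.
#' @export
read_gaze_csv <- function(path, screen = screen_dims()) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = c("participant_id", "video_id")),
                          na.strings = "")
  required <- c("participant_id", "video_id", "t_ms", "x_px", "y_px", "valid")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop_gd(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  }
  for (col in c("t_ms", "x_px", "y_px", "valid")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        # +1 for the header line
        stop_gd(sprintf("malformed value in column '%s' at line %d of %s",
                        col, bad[1] + 1L, path))
      }
      data.table::set(dt, j = col, value = num)
    }
  }
  bad_valid <- which(!dt$valid %in% c(0, 1))
  if (length(bad_valid)) {
    stop_gd(sprintf("column 'valid' must be 0/1; offending line %d of %s",
                    bad_valid[1] + 1L, path))
  }
  gaze_recordings_from_table(as.data.frame(dt), screen = screen)
}

#' Build gaze recordings from a long sample table
#'
#' @param samples data.frame with columns `participant_id`, `video_id`,
#'   `t_ms`, `x_px`, `y_px`, `valid`.
#' @param sampling_rate_hz nominal sampling rate recorded on each recording.
#' @param screen screen bounds.
#' @return list of [gaze_recording()] objects, ordered by (participant, video).
#' @export
gaze_recordings_from_table <- function(samples, sampling_rate_hz = 60,
                                       screen = screen_dims()) {
  key <- paste(samples$participant_id, samples$video_id, sep = "\r")
  idx <- split(seq_len(nrow(samples)), key)
  idx <- idx[order(names(idx))]
  lapply(idx, function(i) {
    s <- samples[i, , drop = FALSE]
    gaze_recording(s$participant_id[1], s$video_id[1], s$t_ms,
                   s$x_px, s$y_px, as.logical(s$valid),
                   sampling_rate_hz = sampling_rate_hz, screen = screen)
  })
}

#' Write gaze recordings to the CSV dialect
#'
#' Inverse of [read_gaze_csv()]: round-tripping reproduces all sample fields.
#'
#' @param recordings list of [gaze_recording()] objects (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r) {
    data.frame(participant_id = r$participant_id, video_id = r$video_id,
               r$samples[c("t_ms", "x_px", "y_px")],
               valid = as.integer(r$samples$valid))
  })
  out <- do.call(rbind, tabs)
  data.table::fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write the video manifest
#'
#' The manifest lists each stimulus video with its advert category (FUN,
#' SPORT, PRODUCT or CONTROL) and duration in seconds.
#'
#' @param path CSV path with header `video_id,category,duration_s`.
#' @return data.frame with those columns.
#' @export
read_video_manifest <- function(path) {
  m <- utils::read.csv(path, colClasses = c(video_id = "character",
                                            category = "character"))
  assert_that(all(c("video_id", "category", "duration_s") %in% names(m)),
              "manifest must have columns video_id, category, duration_s")
  m
}

#' @rdname read_video_manifest
#' @param manifest data.frame as returned by [read_video_manifest()].
#' @export
write_video_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Map sample times (ms) to 0-indexed frames under half-open windows
# [f/fps, (f+1)/fps). The tiny tolerance keeps samples that sit exactly on
# a window boundary in the correct frame despite binary rounding of t/fps.
time_to_frame <- function(t_ms, fps) {
  as.integer(floor(t_ms / 1000 * fps + 1e-9))
}

#' Resample a gaze recording to video frames
#'
#' Frame `f` (0-indexed) covers the half-open interval `[f/fps, (f+1)/fps)`
#' seconds from video onset. A frame's position is the arithmetic mean of
#' the valid samples falling in its window, and missing when none do; the
#' result is invariant to within-frame sample order.
#'
#' @param recording a [gaze_recording()].
#' @param fps video frame rate (frames per second).
#' @param n_frames optional frame count; defaults to the number of frame
#'   windows needed to cover the last sample.
#' @return object of class `frame_series`: list with numeric vectors `x`,
#'   `y` of length `n_frames` (`NA` = no valid sample) plus ids and `fps`.
#' @export
resample_to_frames <- function(recording, fps = 30, n_frames = NULL) {
  assert_that(inherits(recording, "gaze_recording"), "need a gaze_recording")
  assert_that(fps > 0, "fps must be positive")
  s <- recording$samples
  assert_that(nrow(s) > 0, "recording has no samples")
  frame <- time_to_frame(s$t_ms, fps)
  if (is.null(n_frames)) n_frames <- max(frame) + 1L
  x <- rep(NA_real_, n_frames)
  y <- rep(NA_real_, n_frames)
  ok <- s$valid & frame < n_frames
  if (any(ok)) {
    f1 <- factor(frame[ok], levels = 0:(n_frames - 1))
    x <- as.numeric(tapply(s$x_px[ok], f1, mean))
    y <- as.numeric(tapply(s$y_px[ok], f1, mean))
  }
  structure(list(participant_id = recording$participant_id,
                 video_id = recording$video_id,
                 fps = fps, x = x, y = y),
            class = "frame_series")
}

#' Assemble per-participant frame series into a frame-by-participant matrix
#'
#' Columns are ordered by sorted participant id; shorter series are padded
#' with missing frames so the grid spans the longest series.
#'
#' @param columns list of `frame_series` objects for one video.
#' @param video_id video identifier; defaults to the (unique) id carried by
#'   the columns.
#' @return a `frame_gaze_matrix`: list with `video_id`, `fps`, `n_frames`,
#'   `participants`, and `n_frames x n_participants` matrices `x` and `y`.
#' @export
assemble_matrix <- function(columns, video_id = NULL) {
  assert_that(length(columns) >= 1, "need at least one column")
  vids <- unique(vapply(columns, `[[`, "", "video_id"))
  if (is.null(video_id)) {
    assert_that(length(vids) == 1, "columns come from different videos")
    video_id <- vids
  }
  fps <- unique(vapply(columns, `[[`, 0, "fps"))
  assert_that(length(fps) == 1, "columns have differing fps")
  ids <- unname(vapply(columns, `[[`, "", "participant_id"))
  if (anyDuplicated(ids)) {
    stop_gd(sprintf("duplicate participant '%s' for video %s",
                    ids[duplicated(ids)][1], video_id))
  }
  ord <- order(ids)
  columns <- columns[ord]
  ids <- ids[ord]
  n_frames <- max(vapply(columns, function(c) length(c$x), 0L))
  pad <- function(v) c(v, rep(NA_real_, n_frames - length(v)))
  x <- vapply(columns, function(c) pad(c$x), numeric(n_frames))
  y <- vapply(columns, function(c) pad(c$y), numeric(n_frames))
  dim(x) <- dim(y) <- c(n_frames, length(ids))
  colnames(x) <- colnames(y) <- ids
  frame_gaze_matrix(video_id, fps, x, y)
}

#' Construct a frame-by-participant gaze matrix
#'
#' @param video_id video identifier.
#' @param fps frame rate the grid was built at.
#' @param x,y numeric `n_frames x n_participants` matrices of gaze
#'   coordinates (`NA` = missing), with participant ids as column names.
#' @return object of class `frame_gaze_matrix`.
#' @export
frame_gaze_matrix <- function(video_id, fps, x, y) {
  assert_that(all(dim(x) == dim(y)), "x and y grids must have equal shape")
  assert_that(!is.null(colnames(x)), "participant ids required as colnames")
  assert_that(identical(is.na(x), is.na(y)),
              "x and y must be missing in the same cells")
  structure(list(video_id = as.character(video_id), fps = fps,
                 n_frames = nrow(x), participants = colnames(x),
                 x = x, y = y),
            class = "frame_gaze_matrix")
}

#' @export
print.frame_gaze_matrix <- function(x, ...) {
  cat(sprintf("<frame_gaze_matrix> video %s: %d frames x %d participants (%.1f%% missing) @ %g fps\n",
              x$video_id, x$n_frames, length(x$participants),
              100 * mean(is.na(x$x)), x$fps))
  invisible(x)
}

#' Subset a frame gaze matrix by participant
#'
#' @param matrix a `frame_gaze_matrix`.
#' @param participants ids to keep (all must be present).
#' @return a `frame_gaze_matrix` restricted to those participants.
#' @export
subset_participants <- function(matrix, participants) {
  missing_p <- setdiff(participants, matrix$participants)
  assert_that(length(missing_p) == 0,
              sprintf("unknown participant(s): %s",
                      paste(utils::head(missing_p, 3), collapse = ", ")))
  frame_gaze_matrix(matrix$video_id, matrix$fps,
                    matrix$x[, participants, drop = FALSE],
                    matrix$y[, participants, drop = FALSE])
}

#' Convert a long gaze-sample table into per-video frame matrices
#'
#' Vectorised equivalent of calling [resample_to_frames()] on every
#' recording and [assemble_matrix()] per video; used for cohort-scale data.
#'
#' @param samples long data.frame of gaze samples (columns as in the CSV
#'   dialect) or a list of [gaze_recording()] objects.
#' @param fps video frame rate.
#' @return named list of `frame_gaze_matrix`, one per video (sorted id).
#' @export
build_frame_matrices <- function(samples, fps = 30) {
  if (is.list(samples) && !is.data.frame(samples)) {
    samples <- do.call(rbind, lapply(samples, function(r) {
      data.frame(participant_id = r$participant_id, video_id = r$video_id,
                 r$samples)
    }))
  }
  dt <- data.table::as.data.table(samples)
  dt[, frame := time_to_frame(t_ms, fps)]
  nf <- dt[, .(n_frames = max(frame) + 1L), by = video_id]
  agg <- dt[valid == TRUE,
            .(x = mean(x_px), y = mean(y_px)),
            by = .(video_id, participant_id, frame)]
  out <- list()
  for (vid in sort(unique(dt$video_id))) {
    nfr <- nf[video_id == vid, n_frames]
    ids <- sort(unique(dt[video_id == vid, participant_id]))
    a <- agg[video_id == vid]
    x <- matrix(NA_real_, nfr, length(ids), dimnames = list(NULL, ids))
    y <- x
    ij <- cbind(a$frame + 1L, match(a$participant_id, ids))
    x[ij] <- a$x
    y[ij] <- a$y
    out[[vid]] <- frame_gaze_matrix(vid, fps, x, y)
  }
  out
}

# data.table NSE columns
utils::globalVariables(c("frame", "video_id", "t_ms", "valid", "x_px",
                         "y_px", "participant_id", "n_frames"))
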