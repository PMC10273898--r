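#' Default GACS item-to-subscale map
#'
#' The Gambling Craving Scale has 9 items in three subscales (anticipation,
#' desire, relief). Published versions do not fix a canonical item order for
#' a data export, so the mapping is a convention of this package: items 1-3
#' anticipation, 4-6 desire, 7-9 relief. Override by passing your own map
#' wherever a `subscale_map` argument is accepted.
#'
#' @return named character vector of length 9: item index -> subscale.
#' @export
gacs_default_map <- function() {
  stats::setNames(rep(c("anticipation", "desire", "relief"), each = 3),
                  paste0("item", 1:9))
}

validate_subscale_map <- function(subscale_map) {
  assert_that(length(subscale_map) == 9, "subscale map must cover 9 items")
  tab <- table(factor(subscale_map,
                      levels = c("anticipation", "desire", "relief")))
  assert_that(all(tab == 3), "each subscale must have exactly 3 items")
  invisible(subscale_map)
}

#' Score a GACS response
#'
#' Subscale scores are sums of their three items; the total is the sum of
#' all nine. With items on a 1-7 Likert scale, totals range 9-63.
#'
#' @param items integer vector of 9 item responses, each in 1..7, in
#'   questionnaire order.
#' @param subscale_map item-to-subscale assignment; see [gacs_default_map()].
#' @return list with `total`, `anticipation`, `desire`, `relief`.
#' @export
score_gacs <- function(items, subscale_map = gacs_default_map()) {
  assert_that(length(items) == 9, "GACS has exactly 9 items")
  assert_that(!anyNA(items) && all(items == round(items)) &&
                all(items >= 1 & items <= 7),
              "items must be integers in 1..7")
  validate_subscale_map(subscale_map)
  sub <- vapply(c("anticipation", "desire", "relief"),
                function(s) sum(items[subscale_map == s]), 0)
  c(list(total = sum(items)), as.list(sub))
}

#' Score a table of GACS responses
#'
#' @param responses data.frame with `participant_id` and columns
#'   `item1`..`item9`.
#' @inheritParams score_gacs
#' @return data.frame with participant_id, total and subscale scores.
#' @export
score_gacs_table <- function(responses, subscale_map = gacs_default_map()) {
  cols <- paste0("item", 1:9)
  assert_that(all(c("participant_id", cols) %in% names(responses)),
              "need participant_id and item1..item9 columns")
  scores <- lapply(seq_len(nrow(responses)), function(i) {
    as.data.frame(score_gacs(as.numeric(responses[i, cols]), subscale_map))
  })
  cbind(data.frame(participant_id = as.character(responses$participant_id)),
        do.call(rbind, scores))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the total score, all with the unbiased (n-1) denominator.
#'
#' @param item_matrix numeric matrix, participants in rows, items in columns.
#' @return alpha (scalar). Errors if the total-score variance is zero.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  assert_that(k >= 2 && nrow(item_matrix) >= 2,
              "need at least 2 items and 2 participants")
  assert_that(!anyNA(item_matrix), "item matrix must be complete")
  total_var <- stats::var(rowSums(item_matrix))
  if (total_var == 0) stop_gd("total-score variance is zero; alpha undefined")
  item_var <- sum(apply(item_matrix, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Median split of total scores into low/high groups
#'
#' The split value is the sample median of the totals. Under the default
#' ties-to-low policy a participant is labelled `high` iff their total is
#' strictly greater than the median; `ties_to = "high"` labels `high` at
#' greater-or-equal.
#'
#' @param totals named numeric vector (names = participant ids) or
#'   data.frame with `participant_id` and `total`.
#' @param ties_to where participants scoring exactly the median go:
#'   `"low"` (default) or `"high"`.
#' @return object of class `group_assignment`: data.frame with
#'   `participant_id` and `label` (`low`/`high`), with attributes
#'   `split_value` and `ties_to`.
#' @export
median_split <- function(totals, ties_to = c("low", "high")) {
  ties_to <- match.arg(ties_to)
  if (is.data.frame(totals)) {
    totals <- stats::setNames(totals$total, totals$participant_id)
  }
  assert_that(length(totals) >= 2, "need at least 2 participants")
  assert_that(!is.null(names(totals)), "totals must be named by participant")
  if (length(unique(totals)) == 1) {
    stop_gd("all totals identical: degenerate median split")
  }
  med <- stats::median(totals)
  high <- if (ties_to == "low") totals > med else totals >= med
  out <- data.frame(participant_id = names(totals),
                    label = ifelse(high, "high", "low"),
                    stringsAsFactors = FALSE)
  if (!all(c("low", "high") %in% out$label)) {
    warning("degenerate split: one group is empty", call. = FALSE)
  }
  structure(out, split_value = med, ties_to = ties_to,
            class = c("group_assignment", "data.frame"))
}

#' Group labels as a named vector
#'
#' @param groups a `group_assignment`.
#' @param participants optional subset/order of participant ids.
#' @return named character vector of `low`/`high` labels.
#' @export
group_labels <- function(groups, participants = NULL) {
  lab <- stats::setNames(groups$label, groups$participant_id)
  if (!is.null(participants)) {
    missing_p <- setdiff(participants, names(lab))
    assert_that(length(missing_p) == 0,
                sprintf("no group label for: %s",
                        paste(utils::head(missing_p, 3), collapse = ", ")))
    lab <- lab[participants]
  }
  lab
}

#' Read a questionnaire CSV
#'
#' @param path CSV with header `participant_id,item1,...,item9`.
#' @return data.frame of responses.
#' @export
read_gacs_csv <- function(path) {
  utils::read.csv(path, colClasses = c(participant_id = "character"))
}

#' @rdname read_gacs_csv
#' @param responses response data.frame to write.
#' @export
write_gacs_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
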