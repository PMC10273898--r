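# Independent brute-force oracles, kept deliberately naive (loops and
# explicit sums) so they share no code path with the implementation.

oracle_mean2d <- function(x, y) {
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && !is.na(y[i])) {
      sx <- sx + x[i]; sy <- sy + y[i]; n <- n + 1
    }
  }
  c(sx / n, sy / n)
}

oracle_dist <- function(x, y, centre) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- sqrt((x[i] - centre[1])^2 + (y[i] - centre[2])^2)
  }
  out
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  ss1 <- 0; for (v in a) ss1 <- ss1 + (v - m1)^2
  ss2 <- 0; for (v in b) ss2 <- ss2 + (v - m2)^2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

oracle_anova <- function(values, groups) {
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_between <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
  }
  ss_within <- ss_total - ss_between
  dfb <- length(unique(groups)) - 1
  dfw <- length(values) - length(unique(groups))
  f <- (ss_between / dfb) / (ss_within / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE),
       dfb = dfb, dfw = dfw, eta2 = ss_between / ss_total)
}

oracle_alpha <- function(mat) {
  k <- ncol(mat); n <- nrow(mat)
  varcol <- function(v) {
    m <- sum(v) / n
    s <- 0; for (x in v) s <- s + (x - m)^2
    s / (n - 1)
  }
  totals <- numeric(n)
  for (i in seq_len(n)) totals[i] <- sum(mat[i, ])
  item_var <- 0
  for (j in seq_len(k)) item_var <- item_var + varcol(mat[, j])
  k / (k - 1) * (1 - item_var / varcol(totals))
}
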