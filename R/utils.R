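#' @importFrom data.table := fread fwrite as.data.table set
#' @importFrom stats rnorm runif rbinom
NULL

.datatable.aware <- TRUE

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their randomness from a single
#' master seed; independent stages (cohorts, repetitions, videos) get
#' deterministic child seeds via a multiplicative congruential mix so that
#' changing one stage's stream never perturbs another's.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer stream indices (e.g.
#'   repetition number, video number).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (idx in c(...)) {
    # Lehmer step then add the index; all arithmetic exact in doubles
    s <- (s * 48271) %% m
    s <- (s + as.numeric(idx) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gd <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_gd(msg)
}
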