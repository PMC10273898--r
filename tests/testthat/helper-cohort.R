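# Small, fast synthetic cohorts for unit tests. Acceptance tests use the
# full-size defaults; these shrink every dimension so a whole pipeline run
# takes well under a second.

small_sim_config <- function(seed = 1, ...) {
  args <- list(n_participants = 24, group_sizes = c(low = 12, high = 12),
               n_videos = 4, duration_s = 6, fps = 20,
               sampling_rate_hz = 40, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(small_sim_config(seed, ...))
}

cohort_groups <- function(cohort) {
  median_split(score_gacs_table(cohort$gacs))
}

true_group_assignment <- function(cohort) {
  structure(data.frame(participant_id = names(cohort$truth$group),
                       label = unname(cohort$truth$group),
                       stringsAsFactors = FALSE),
            split_value = NA_real_, ties_to = "low",
            class = c("group_assignment", "data.frame"))
}
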