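# Independent normal-equations OLS solver: the oracle against which every
# model fit in the package is checked. Deliberately naive.
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

make_ratings <- function(taste, health, pid = "P1") {
  data.frame(participant_id = pid, item_id = seq_along(taste),
             taste = as.integer(taste), health = as.integer(health))
}

make_trials <- function(target, referent, preference, rt = 1000, pid = "P1") {
  data.frame(participant_id = pid, trial_index = seq_along(target),
             target_item_id = target, referent_item_id = referent,
             preference = as.integer(preference),
             rt_ms = rep_len(rt, length(target)))
}

# One default-condition cohort (n = 500, 49 trials, seed 1), scored once and
# cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())
default_cohort_scored <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  cohort <- generate_cohort(sim_config(seed = 1))
  scores <- score_tfeq(cohort$tfeq_items)
  task <- suppressMessages(score_task(cohort$ratings, cohort$trials))
  cleaned <- clean_participants(cohort$demographics, cohort$trials,
                                cohort$ratings)
  .fixture_cache$default <- list(cohort = cohort, scores = scores,
                                 task = task, cleaned = cleaned)
  .fixture_cache$default
}
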