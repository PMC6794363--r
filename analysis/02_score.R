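#!/usr/bin/env Rscript
# Step 2 — clean the sample and score questionnaire + task.
#
# Reads results/cohort/, applies the plausibility screen, scores the
# TFEQ-R18 (0-100 subscales, disinhibition composite, Cronbach's alpha),
# scores the decision-making task (referent-anchored difference scores,
# per-participant sensitivities, preference proportions) and trims RT
# outliers at +/-2.2 SD per participant. Writes results/scores/.

library(dietchoice)

cohort <- read_cohort("results/cohort")
cleaned <- clean_participants(cohort$demographics, cohort$trials,
                              cohort$ratings)
cat("Retained", nrow(cleaned$demographics), "of", nrow(cohort$demographics),
    "participants;", nrow(cleaned$exclusions), "excluded\n")

keep <- cleaned$demographics$participant_id
tfeq_items <- cohort$tfeq_items[cohort$tfeq_items$participant_id %in% keep, ]
ratings <- cohort$ratings[cohort$ratings$participant_id %in% keep, ]
trials <- cohort$trials[cohort$trials$participant_id %in% keep, ]

scores <- score_tfeq(tfeq_items)
map <- tfeq_item_map()
alphas <- sapply(c("cr", "ue", "ee"), function(s)
  cronbach_alpha(tfeq_items[paste0("tfeq_", map$item[map$subscale == s])]))
cat(sprintf("Cronbach's alpha: CR %.2f, UE %.2f, EE %.2f\n",
            alphas["cr"], alphas["ue"], alphas["ee"]))
cat(sprintf("Scored UE-EE correlation: %.3f -> disinhibition composite used\n",
            cor(scores$ue, scores$ee)))

task <- score_task(ratings, trials)
cat(sprintf("RT trimming removed %d of %d trials (%.2f%%)\n",
            sum(!task$derived$rt_retained), nrow(task$derived),
            100 * mean(!task$derived$rt_retained)))
cat(sprintf("Mean retained RT: %.0f ms\n",
            mean(task$derived$rt_ms[task$derived$rt_retained])))

dir.create("results/scores", recursive = TRUE, showWarnings = FALSE)
wr <- function(df, name) write.table(
  df, file.path("results/scores", paste0(name, ".tsv")),
  sep = "\t", row.names = FALSE, quote = FALSE)
wr(cleaned$demographics, "demographics_clean")
wr(cleaned$exclusions, "exclusions")
wr(scores, "tfeq_scores")
wr(task$outcomes, "task_outcomes")
wr(task$derived, "trials_derived")
wr(task$rt_report, "rt_removal_report")
cat("Score tables in results/scores/\n")
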