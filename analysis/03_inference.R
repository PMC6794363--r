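#!/usr/bin/env Rscript
# Step 3 — covariate screening, outcome models, RT models, moderation.
#
# Reads results/scores/, screens demographics against all outcomes at
# p < 0.10, fits standardized regressions of the four task outcomes on
# cognitive restraint and disinhibited eating, trial-level RT regressions
# on the difference scores, and the median-split / continuous moderation
# analyses. Writes results/analysis/.

library(dietchoice)

rd <- function(name) read.delim(file.path("results/scores",
                                          paste0(name, ".tsv")))
dem <- rd("demographics_clean")
dem$weight_status <- factor(dem$weight_status,
                            levels = c("healthy", "overweight", "obese"))
scores <- rd("tfeq_scores")
outcomes <- rd("task_outcomes")
derived <- rd("trials_derived")

## covariate screening ------------------------------------------------------
rt_mean <- aggregate(list(mean_rt_ms = derived$rt_ms[derived$rt_retained]),
                     by = list(participant_id =
                                 derived$participant_id[derived$rt_retained]),
                     mean)
outcome_tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                      list(outcomes[c("participant_id", "taste_sensitivity",
                                      "health_sensitivity", "prop_healthy",
                                      "prop_tasty")],
                           scores[c("participant_id", "cr", "ue", "ee")],
                           rt_mean))
screen <- screen_covariates(
  dem, outcome_tab,
  vars = intersect(c("age", "sex", "bmi", "race", "income", "education"),
                   names(dem)))
cat("Covariates selected at p < 0.10:",
    paste(screen$covariates, collapse = ", "), "\n")

## descriptives by weight status -------------------------------------------
desc <- describe_by_weight_status(dem, scores)

## outcome models -----------------------------------------------------------
ptab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
               list(outcomes[outcomes$sensitivity_ok, ], scores, dem))
om <- fit_outcome_models(ptab, screen$covariates)
b <- function(out, pred) om$estimate[
  om$model == paste0(out, " ~ ", pred, " (unadjusted)") & om$term == pred]
cat(sprintf(paste0(
  "Standardized unadjusted slopes:\n",
  "  restraint    -> health sensitivity %+.2f, taste sensitivity %+.2f\n",
  "  disinhibition-> health sensitivity %+.2f, taste sensitivity %+.2f\n"),
  b("health_sensitivity", "cr"), b("taste_sensitivity", "cr"),
  b("health_sensitivity", "disinhibited"),
  b("taste_sensitivity", "disinhibited")))

## reaction-time models -------------------------------------------------------
rtm <- fit_rt_models(derived, scores, dem, screen$covariates)
joint <- rtm[rtm$model == "rt_ms ~ health_diff + taste_diff (adjusted)", ]
bh <- joint$estimate[joint$term == "health_diff"]
bt <- joint$estimate[joint$term == "taste_diff"]
cat(sprintf("Adjusted RT slopes: health %.2f ms/unit, taste %.2f ms/unit\n",
            bh, bt))
cat(sprintf("Full-span (8-unit) speed differences: health %d ms, taste %d ms\n",
            span_effect(bh, 8), span_effect(bt, 8)))

## moderation ----------------------------------------------------------------
mods <- list()
for (m in c("cr", "disinhibited"))
  for (d in c("health", "taste", "health_minus_taste"))
    for (f in c("median", "continuous"))
      mods[[paste(m, d, f, sep = ".")]] <- moderation_analysis(
        derived, scores, m, d, f, dem, screen$covariates)
mod_tab <- do.call(rbind, lapply(names(mods), function(nm) {
  x <- mods[[nm]]
  data.frame(analysis = nm, interaction = x$interaction$estimate,
             p = x$interaction$p, flagged = x$flagged,
             low_slope = if (is.null(x$strata)) NA else
               x$strata$low$estimate[x$strata$low$term == "diff_score"],
             high_slope = if (is.null(x$strata)) NA else
               x$strata$high$estimate[x$strata$high$term == "diff_score"])
}))
cm <- mods[["cr.health.median"]]
cat(sprintf(paste0(
  "Median-split restraint x health difference: low stratum %.2f, high ",
  "stratum %.2f ms/unit (interaction p = %.3g%s)\n"),
  cm$strata$low$estimate[cm$strata$low$term == "diff_score"],
  cm$strata$high$estimate[cm$strata$high$term == "diff_score"],
  cm$interaction$p, if (cm$flagged) ", flagged" else ""))

dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
wr <- function(df, name) write.table(
  df, file.path("results/analysis", paste0(name, ".tsv")),
  sep = "\t", row.names = FALSE, quote = FALSE)
wr(screen$table, "covariate_screen")
wr(desc$continuous, "descriptives_continuous")
wr(desc$categorical, "descriptives_categorical")
wr(om, "outcome_models")
wr(rtm, "rt_models")
wr(mod_tab, "moderation")
cat("Model tables in results/analysis/\n")
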