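#' End-to-end pipeline: simulate, score, infer, report
#'
#' Runs the stages in study order — (optionally) simulate a cohort, clean
#' participants, score the questionnaire, score the decision-making task
#' with RT trimming, screen covariates, fit the outcome and reaction-time
#' models, and run the moderation analyses — with validation between stages.
#' All result tables are written as tab-separated text under `out_dir`,
#' together with the exclusion report and a `manifest.yaml` recording the
#' configuration, seed, input checksums and per-stage row counts. Identical
#' config and inputs give byte-identical outputs.
#'
#' @param mode `"simulate"` (generate and write a cohort only), `"analyze"`
#'   (read tables from `input_dir` and analyse), or `"full"` (simulate in
#'   memory, then analyse).
#' @param sim a [sim_config()] for modes `"simulate"` and `"full"`.
#' @param input_dir directory of cohort tables for mode `"analyze"`
#'   (as written by [write_cohort()]).
#' @param out_dir output directory; created if missing.
#' @param rt_k,rt_unit RT trimming rule, see [filter_rt_outliers()].
#' @param collapse use the collapsed health-minus-taste score in the
#'   moderation analyses.
#' @param referent_metric tie metric for [select_referent()] (recorded in
#'   the manifest; the referent is fixed by the trials table, so this only
#'   matters when simulating).
#' @param flag_alpha interaction flag threshold.
#' @param verbose print stage-level progress.
#' @return Invisibly, the run manifest (a list). In analysis modes the
#'   manifest's `results` element holds the in-memory tables.
#' @export
run_pipeline <- function(mode = c("full", "simulate", "analyze"),
                         sim = sim_config(), input_dir = NULL,
                         out_dir = tempfile("dietchoice_run_"),
                         rt_k = 2.2, rt_unit = "participant",
                         collapse = TRUE, referent_metric = "euclidean",
                         flag_alpha = 0.10, verbose = TRUE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message("[dietchoice] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(mode = mode, rt_k = rt_k, rt_unit = rt_unit,
                   collapse = collapse, referent_metric = referent_metric,
                   flag_alpha = flag_alpha, rows = list())

  if (mode %in% c("simulate", "full")) {
    say("simulating cohort (n = ", sim$n_participants, ", seed = ",
        sim$seed, ")")
    cohort <- generate_cohort(sim)
    manifest$seed <- sim$seed
    if (mode == "simulate") {
      write_cohort(cohort, out_dir)
      manifest$rows <- lapply(cohort[c("demographics", "tfeq_items",
                                       "ratings", "trials")], nrow)
      yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
      say("wrote cohort tables to ", out_dir)
      return(invisible(manifest))
    }
    tables <- cohort[c("demographics", "tfeq_items", "ratings", "trials")]
  } else {
    if (is.null(input_dir)) stop("mode 'analyze' needs input_dir", call. = FALSE)
    say("reading tables from ", input_dir)
    tables <- read_cohort(input_dir)
    tsvs <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$input_checksums <- as.list(tools::md5sum(tsvs))
  }
  validate_trials(tables$trials)
  validate_ratings(tables$ratings)
  manifest$rows$input <- lapply(tables, nrow)

  ## stage: participant cleaning -------------------------------------------
  say("cleaning participants")
  cleaned <- clean_participants(tables$demographics, tables$trials,
                                tables$ratings)
  keep <- cleaned$demographics$participant_id
  say("  retained ", length(keep), " of ", nrow(tables$demographics),
      " participants (", nrow(cleaned$exclusions), " excluded)")
  tfeq_items <- tables$tfeq_items[tables$tfeq_items$participant_id %in% keep, ]
  ratings <- tables$ratings[tables$ratings$participant_id %in% keep, ]
  trials <- tables$trials[tables$trials$participant_id %in% keep, ]
  manifest$rows$cleaned <- list(participants = length(keep),
                                excluded = nrow(cleaned$exclusions))

  ## stage: questionnaire scoring ------------------------------------------
  say("scoring TFEQ-R18")
  scores <- score_tfeq(tfeq_items)
  alphas <- sapply(c("cr", "ue", "ee"), function(s) {
    cols <- paste0("tfeq_", tfeq_item_map()$item[tfeq_item_map()$subscale == s])
    cronbach_alpha(tfeq_items[cols])
  })
  say("  Cronbach's alpha: ", paste(sprintf("%s = %.2f", names(alphas),
                                            alphas), collapse = ", "))

  ## stage: task scoring -----------------------------------------------------
  say("scoring decision-making task")
  task <- score_task(ratings, trials, rt_k = rt_k, rt_unit = rt_unit)
  say("  ", sum(!task$derived$rt_retained), " RT outlier trial(s) trimmed")
  manifest$rows$task <- list(outcomes = nrow(task$outcomes),
                             derived = nrow(task$derived),
                             rt_trimmed = sum(!task$derived$rt_retained))

  ## stage: covariate screening ----------------------------------------------
  say("screening covariates")
  mean_rt <- stats::aggregate(
    list(mean_rt_ms = task$derived$rt_ms[task$derived$rt_retained]),
    by = list(participant_id =
                task$derived$participant_id[task$derived$rt_retained]),
    mean)
  outcome_tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                        list(task$outcomes[c("participant_id",
                                             "taste_sensitivity",
                                             "health_sensitivity",
                                             "prop_healthy", "prop_tasty")],
                             scores[c("participant_id", "cr", "ue", "ee")],
                             mean_rt))
  dem <- cleaned$demographics
  screen <- screen_covariates(
    dem, outcome_tab,
    vars = intersect(c("age", "sex", "bmi", "race", "income", "education"),
                     names(dem)))
  say("  covariates selected: ",
      if (length(screen$covariates)) paste(screen$covariates, collapse = ", ")
      else "(none)")

  ## stage: outcome models -----------------------------------------------------
  say("fitting outcome models")
  ptab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                 list(task$outcomes[task$outcomes$sensitivity_ok, ],
                      scores, dem))
  outcome_models <- fit_outcome_models(ptab, screen$covariates)

  ## stage: reaction-time models ----------------------------------------------
  say("fitting reaction-time models")
  rt_models <- fit_rt_models(task$derived, scores, dem, screen$covariates)

  say("running moderation analyses")
  mods <- list()
  for (m in c("cr", "disinhibited"))
    for (d in c("health", "taste", "health_minus_taste"))
      for (f in c("median", "continuous"))
        mods[[paste(m, d, f, sep = ".")]] <- moderation_analysis(
          task$derived, scores, moderator = m, difference = d, form = f,
          demographics = dem, covariates = screen$covariates,
          flag_alpha = flag_alpha, collapse = collapse)
  mod_tab <- do.call(rbind, lapply(names(mods), function(nm) {
    x <- mods[[nm]]
    data.frame(analysis = nm, moderator = x$moderator,
               difference = x$difference, form = x$form,
               interaction = x$interaction$estimate,
               se = x$interaction$se, p = x$interaction$p,
               flagged = x$flagged,
               low_slope = if (is.null(x$strata)) NA_real_ else
                 x$strata$low$estimate[x$strata$low$term == "diff_score"],
               high_slope = if (is.null(x$strata)) NA_real_ else
                 x$strata$high$estimate[x$strata$high$term == "diff_score"])
  }))

  say("writing descriptives and result tables")
  desc <- describe_by_weight_status(dem, scores)

  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(cleaned$exclusions, "exclusions")
  wr(scores, "tfeq_scores")
  wr(task$outcomes, "task_outcomes")
  wr(task$derived, "trials_derived")
  wr(task$rt_report, "rt_removal_report")
  wr(screen$table, "covariate_screen")
  wr(outcome_models, "outcome_models")
  wr(rt_models, "rt_models")
  wr(mod_tab, "moderation")
  wr(desc$continuous, "descriptives_continuous")
  wr(desc$categorical, "descriptives_categorical")

  manifest$covariates <- screen$covariates
  manifest$alphas <- as.list(round(alphas, 4))
  manifest$results <- list(
    scores = scores, outcomes = task$outcomes, derived = task$derived,
    exclusions = cleaned$exclusions, demographics = dem,
    covariates = screen$covariates, outcome_models = outcome_models,
    rt_models = rt_models, moderation = mods, moderation_table = mod_tab,
    descriptives = desc, alphas = alphas
  )
  yaml::write_yaml(manifest[setdiff(names(manifest), "results")],
                   file.path(out_dir, "run_manifest.yaml"))
  say("done; results in ", out_dir)
  invisible(manifest)
}
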