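#' Classify weight status from BMI
#'
#' Standard CDC adult cut points: healthy weight up to 24.9, overweight
#' 25-29.9, obese 30 and above.
#'
#' @param bmi numeric vector, kg/m^2.
#' @return Factor with levels `healthy`, `overweight`, `obese`.
#' @export
assign_weight_status <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
      labels = c("healthy", "overweight", "obese"))
}

#' Clean the participant sample
#'
#' Applies the study's plausibility screen: participants reporting a height
#' below a floor (default 2 feet = 0.6096 m) or a computed BMI below a
#' plausibility floor (default 10) are removed, as are invariant responders —
#' participants whose dietary-task response streams carry zero variance
#' (every preference identical and, when ratings are supplied, every taste
#' rating identical and every health rating identical). BMI is computed as
#' `weight / height^2` and weight status assigned from it.
#'
#' @param demographics data.frame with `participant_id`, `height_m`,
#'   `weight_kg` (a precomputed `bmi` column is ignored and recomputed).
#' @param trials trials table with `participant_id` and `preference`.
#' @param ratings optional ratings table; when present it joins the
#'   invariant-responder check.
#' @param min_height_m height plausibility floor in metres.
#' @param bmi_floor BMI plausibility floor.
#' @return A list with `demographics` (retained rows, plus `bmi` and
#'   `weight_status`) and `exclusions` (one row per removed participant:
#'   `participant_id`, `rule`).
#' @export
clean_participants <- function(demographics, trials, ratings = NULL,
                               min_height_m = 0.6096, bmi_floor = 10) {
  stopifnot(all(c("participant_id", "height_m", "weight_kg") %in%
                  names(demographics)))
  d <- demographics
  d$bmi <- d$weight_kg / d$height_m^2
  d$weight_status <- assign_weight_status(d$bmi)

  rule <- rep(NA_character_, nrow(d))
  rule[is.na(rule) & d$height_m < min_height_m] <- "implausible_height"
  rule[is.na(rule) & d$bmi < bmi_floor] <- "implausible_bmi"

  invariant <- vapply(d$participant_id, function(pid) {
    pref <- trials$preference[trials$participant_id == pid]
    if (length(pref) == 0L) return(FALSE)
    flat <- length(unique(pref)) == 1L
    if (flat && !is.null(ratings)) {
      ra <- ratings[ratings$participant_id == pid, , drop = FALSE]
      flat <- nrow(ra) > 0L && length(unique(ra$taste)) == 1L &&
        length(unique(ra$health)) == 1L
    }
    flat
  }, logical(1))
  rule[is.na(rule) & invariant] <- "invariant_responder"

  exclusions <- data.frame(participant_id = d$participant_id[!is.na(rule)],
                           rule = rule[!is.na(rule)])
  kept <- d[is.na(rule), , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) stop("no participants survive cleaning", call. = FALSE)
  list(demographics = kept, exclusions = exclusions)
}

zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant variable", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

# Indicator-code the categorical columns of a demographics table; the
# reference level of each factor is its most frequent level.
code_demographics <- function(demographics, vars) {
  out <- demographics["participant_id"]
  coding <- list()
  for (v in vars) {
    x <- demographics[[v]]
    if (is.numeric(x)) {
      out[[v]] <- x
      coding[[v]] <- "numeric"
    } else {
      tab <- sort(table(x), decreasing = TRUE)
      levs <- names(tab)
      for (lv in levs[-1L]) out[[paste0(v, ".", lv)]] <- as.numeric(x == lv)
      coding[[v]] <- paste0("indicator vs reference '", levs[1L], "'")
    }
  }
  attr(out, "coding") <- coding
  out
}

#' Screen demographic variables as candidate covariates
#'
#' Pairwise Pearson correlations between every demographic variable and
#' every outcome; categorical demographics enter through indicator coding
#' (reference = most frequent level). A demographic variable is selected as
#' a covariate if any of its correlations has `p < alpha` (default 0.10).
#' Constant variables are skipped with a warning.
#'
#' @param demographics participant-level data.frame with `participant_id`.
#' @param outcomes participant-level data.frame with `participant_id` and
#'   numeric outcome columns.
#' @param vars demographic variables to screen; default all non-id columns.
#' @param alpha selection threshold on the correlation p value.
#' @return A list with `covariates` (selected demographic variable names),
#'   `table` (every pair's r and p) and `coding` (how categoricals were
#'   numerically coded).
#' @export
screen_covariates <- function(demographics, outcomes,
                              vars = setdiff(names(demographics), "participant_id"),
                              alpha = 0.10) {
  coded <- code_demographics(demographics, vars)
  merged <- merge(coded, outcomes, by = "participant_id")
  if (nrow(merged) < 3L) stop("need at least 3 complete cases", call. = FALSE)
  out_vars <- setdiff(names(outcomes), "participant_id")
  out_vars <- out_vars[vapply(outcomes[out_vars], is.numeric, logical(1))]
  dem_cols <- setdiff(names(coded), "participant_id")

  rows <- list()
  for (dc in dem_cols) {
    x <- merged[[dc]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning("constant demographic column '", dc, "' skipped", call. = FALSE)
      next
    }
    for (ov in out_vars) {
      y <- merged[[ov]]
      if (stats::sd(y, na.rm = TRUE) == 0) {
        warning("constant outcome '", ov, "' skipped", call. = FALSE)
        next
      }
      ct <- stats::cor.test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        demographic = dc, outcome = ov,
        r = unname(ct$estimate), p = ct$p.value
      )
    }
  }
  tab <- do.call(rbind, rows)
  base_var <- sub("\\..*$", "", tab$demographic)
  hit <- unique(base_var[tab$p < alpha])
  list(covariates = intersect(vars, hit), table = tab,
       coding = attr(coded, "coding"))
}

#' Tidy coefficient table from a fitted linear model
#'
#' @param fit an `lm` fit.
#' @param label model label carried into the table.
#' @param standardized logical flag recorded in the table.
#' @param conf_level confidence level for the t-based intervals.
#' @param cluster optional vector of cluster ids (one per model-frame row);
#'   when supplied, standard errors, t, p and CIs come from the
#'   cluster-robust sandwich estimator instead of the OLS variance.
#' @return data.frame with columns `model`, `term`, `estimate`, `se`, `t`,
#'   `p`, `ci_lo`, `ci_hi`, `n_obs`, `standardized`.
#' @export
model_result <- function(fit, label, standardized = FALSE, conf_level = 0.95,
                         cluster = NULL) {
  sm <- summary(fit)$coefficients
  dropped <- setdiff(names(stats::coef(fit)), rownames(sm))
  if (length(dropped))
    warning("model '", label, "': dropped collinear term(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  df <- fit$df.residual
  if (!is.null(cluster)) {
    V <- sandwich::vcovCL(fit, cluster = cluster)
    se <- sqrt(diag(V))[rownames(sm)]
    df <- length(unique(cluster)) - 1L
  }
  tval <- est / se
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  data.frame(
    model = label, term = rownames(sm),
    estimate = est, se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), df = df),
    ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
    n_obs = length(fit$residuals), standardized = standardized,
    row.names = NULL
  )
}

# Build a model frame in which continuous variables are z-scored and
# categorical variables become factors with the most frequent level as
# reference.
standardized_frame <- function(data, vars) {
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stop("missing variable '", v, "'", call. = FALSE)
    if (is.numeric(x)) {
      out[[v]] <- zscore(x)
    } else {
      f <- factor(x)
      out[[v]] <- stats::relevel(f, ref = names(sort(table(f), decreasing = TRUE))[1L])
    }
  }
  out
}

#' Regress task outcomes on eating-behavior scores
#'
#' For each task outcome (taste sensitivity, health sensitivity, proportion
#' healthy preferred, proportion tasty preferred) and each eating-behavior
#' score (cognitive restraint, disinhibited eating), fits an unadjusted
#' simple regression, plus an adjusted model containing both eating-behavior
#' scores and the screened covariates. All continuous variables are z-scored
#' before fitting, so unadjusted slopes are standardized betas (equal to
#' Pearson correlations).
#'
#' @param participant_table merged participant-level data.frame holding the
#'   outcome columns, `cr`, `disinhibited`, and any covariate columns.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param outcomes outcome column names.
#' @return data.frame of stacked [model_result()] rows; model labels look
#'   like `"health_sensitivity ~ cr (unadjusted)"`.
#' @export
fit_outcome_models <- function(participant_table, covariates = character(0),
                               outcomes = c("taste_sensitivity",
                                            "health_sensitivity",
                                            "prop_healthy", "prop_tasty")) {
  dat <- participant_table
  dat <- dat[stats::complete.cases(dat[c(outcomes, "cr", "disinhibited",
                                         covariates)]), , drop = FALSE]
  res <- list()
  for (out in outcomes) {
    sf <- standardized_frame(dat, c(out, "cr", "disinhibited", covariates))
    for (pred in c("cr", "disinhibited")) {
      f <- stats::as.formula(paste(out, "~", pred))
      res[[length(res) + 1L]] <- model_result(
        stats::lm(f, data = sf),
        paste0(out, " ~ ", pred, " (unadjusted)"), standardized = TRUE)
    }
    f <- stats::as.formula(paste(out, "~ cr + disinhibited",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
    res[[length(res) + 1L]] <- model_result(
      stats::lm(f, data = sf),
      paste0(out, " ~ cr + disinhibited (adjusted)"), standardized = TRUE)
  }
  do.call(rbind, res)
}

# Trial-level analysis frame: preference-indicated, RT-retained trials with
# participant-level scores and covariates replicated across trials.
rt_analysis_frame <- function(derived, scores, demographics = NULL,
                              covariates = character(0)) {
  keep <- derived$preferred_side != "none"
  if ("rt_retained" %in% names(derived)) keep <- keep & derived$rt_retained
  tr <- derived[keep, , drop = FALSE]
  tab <- merge(tr, scores, by = "participant_id")
  if (!is.null(demographics) && length(covariates))
    tab <- merge(tab, demographics[c("participant_id", covariates)],
                 by = "participant_id")
  tab
}

#' Trial-level reaction-time regressions
#'
#' Pooled OLS of single-trial reaction times (ms) on, separately, the health
#' difference score, the taste difference score, cognitive restraint and
#' disinhibited eating — each unadjusted and adjusted for the screened
#' covariates — plus a sensitivity model with the health and taste
#' differences entered simultaneously. Trait scores and continuous
#' covariates are z-scored; the difference scores are left in raw units so
#' their coefficients read as ms per difference unit. Only
#' preference-indicated, RT-retained trials are used.
#'
#' @param derived derived-trials table from [score_task()] (must include
#'   `rt_retained` when trimming is wanted).
#' @param scores participant-level TFEQ scores (`participant_id`, `cr`,
#'   `disinhibited`).
#' @param demographics participant-level covariate source.
#' @param covariates covariate column names in `demographics`.
#' @param cluster_robust use participant-clustered sandwich standard errors
#'   instead of the plain OLS variance. Off by default: pooled OLS matches
#'   the study's approach, but its standard errors understate uncertainty
#'   when slopes vary across participants.
#' @return data.frame of stacked [model_result()] rows.
#' @export
fit_rt_models <- function(derived, scores, demographics = NULL,
                          covariates = character(0), cluster_robust = FALSE) {
  tab <- rt_analysis_frame(derived, scores, demographics, covariates)
  sf <- standardized_frame(tab, c("cr", "disinhibited", covariates))
  sf$rt_ms <- tab$rt_ms
  sf$health_diff <- tab$health_diff
  sf$taste_diff <- tab$taste_diff
  cl <- if (cluster_robust) tab$participant_id else NULL

  cov_rhs <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  fit1 <- function(pred, std) {
    r <- model_result(stats::lm(stats::as.formula(paste("rt_ms ~", pred)),
                                data = sf),
                      paste0("rt_ms ~ ", pred, " (unadjusted)"),
                      standardized = std, cluster = cl)
    a <- model_result(stats::lm(
      stats::as.formula(paste("rt_ms ~", pred, cov_rhs)), data = sf),
      paste0("rt_ms ~ ", pred, " (adjusted)"), standardized = std,
      cluster = cl)
    rbind(r, a)
  }
  res <- rbind(
    fit1("health_diff", FALSE),
    fit1("taste_diff", FALSE),
    fit1("cr", TRUE),
    fit1("disinhibited", TRUE),
    model_result(stats::lm(stats::as.formula(
      paste("rt_ms ~ health_diff + taste_diff", cov_rhs)), data = sf),
      "rt_ms ~ health_diff + taste_diff (adjusted)", standardized = FALSE,
      cluster = cl)
  )
  res
}

#' Moderation of the RT-difference slope by an eating-behavior trait
#'
#' Tests whether cognitive restraint or disinhibited eating modifies the
#' association between reaction time and a trial difference score. In the
#' median-split form, participants at or below the sample median of the
#' moderator form the low stratum; the RT-on-difference slope is estimated
#' within each stratum (covariate adjusted) and the interaction is tested in
#' a pooled model with a difference-by-group term (Wald t, flagged at
#' `p < flag_alpha`, default 0.10). In the continuous form the z-scored
#' moderator replaces the group indicator.
#'
#' @param derived derived-trials table (see [fit_rt_models()]).
#' @param scores participant-level scores with the moderator column.
#' @param moderator `"cr"` or `"disinhibited"`.
#' @param difference `"health"`, `"taste"` or `"health_minus_taste"`.
#' @param form `"median"` or `"continuous"`.
#' @param demographics,covariates covariate source and names.
#' @param flag_alpha significance threshold for the interaction flag.
#' @param collapse for `health_minus_taste`, use the collapsed -5..5 score
#'   (`TRUE`, default) or the raw -8..8 score.
#' @param cluster_robust participant-clustered sandwich standard errors for
#'   the pooled interaction model and stratum slopes; off by default to
#'   match the study's pooled-OLS approach.
#' @return A list of class `"moderation_result"`: `moderator`, `form`,
#'   `difference`, `strata` (per-stratum [model_result()] tables, median
#'   form only), `interaction` (estimate, se, t, p), `flagged`, and
#'   `model` (the pooled-model coefficient table).
#' @export
moderation_analysis <- function(derived, scores,
                                moderator = c("cr", "disinhibited"),
                                difference = c("health", "taste",
                                               "health_minus_taste"),
                                form = c("median", "continuous"),
                                demographics = NULL,
                                covariates = character(0),
                                flag_alpha = 0.10, collapse = TRUE,
                                cluster_robust = FALSE) {
  moderator <- match.arg(moderator)
  difference <- match.arg(difference)
  form <- match.arg(form)
  dcol <- switch(difference, health = "health_diff", taste = "taste_diff",
                 health_minus_taste = if (collapse) "ht_diff" else "ht_diff_raw")
  tab <- rt_analysis_frame(derived, scores, demographics, covariates)
  tab <- tab[!is.na(tab[[dcol]]), , drop = FALSE]
  tab$diff_score <- tab[[dcol]]

  sf <- if (length(covariates)) standardized_frame(tab, covariates)
        else data.frame(row.names = seq_len(nrow(tab)))
  sf$rt_ms <- tab$rt_ms
  sf$diff_score <- tab$diff_score
  sf$participant_id <- tab$participant_id
  clus <- function(d) if (cluster_robust) d$participant_id else NULL
  cov_rhs <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""

  if (form == "median") {
    # the median is taken over participants, not trials; ties go low
    per_part <- tab[!duplicated(tab$participant_id), ]
    med <- stats::median(per_part[[moderator]])
    grp <- ifelse(tab[[moderator]] > med, "high", "low")
    if (length(unique(grp)) < 2L)
      stop("median split produced an empty stratum", call. = FALSE)
    sf$group <- factor(grp, levels = c("low", "high"))
    strata <- lapply(c(low = "low", high = "high"), function(g) {
      d <- sf[sf$group == g, ]
      model_result(stats::lm(stats::as.formula(
        paste("rt_ms ~ diff_score", cov_rhs)), data = d),
        paste0("rt_ms ~ ", dcol, " | ", moderator, "=", g),
        cluster = clus(d))
    })
    pooled <- stats::lm(stats::as.formula(
      paste("rt_ms ~ diff_score * group", cov_rhs)), data = sf)
    int_term <- "diff_score:grouphigh"
  } else {
    sf$mod_z <- zscore(tab[[moderator]])
    strata <- NULL
    pooled <- stats::lm(stats::as.formula(
      paste("rt_ms ~ diff_score * mod_z", cov_rhs)), data = sf)
    int_term <- "diff_score:mod_z"
  }
  ptab <- model_result(pooled, paste0("rt_ms ~ ", dcol, " x ", moderator,
                                      " (", form, ")"), cluster = clus(sf))
  irow <- ptab[ptab$term == int_term, ]
  if (nrow(irow) != 1L) stop("interaction term missing from pooled model",
                             call. = FALSE)
  structure(list(
    moderator = moderator, form = form, difference = difference,
    strata = strata,
    interaction = list(estimate = irow$estimate, se = irow$se,
                       t = irow$t, p = irow$p),
    flagged = irow$p < flag_alpha,
    model = ptab
  ), class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  cat("Moderation of rt ~ ", x$difference, " difference by ", x$moderator,
      " (", x$form, ")\n", sep = "")
  if (!is.null(x$strata)) {
    for (g in names(x$strata)) {
      s <- x$strata[[g]]
      s <- s[s$term == "diff_score", ]
      cat(sprintf("  %s stratum slope: %.2f ms/unit (p = %.3g)\n",
                  g, s$estimate, s$p))
    }
  }
  cat(sprintf("  interaction: %.3f (SE %.3f), p = %.3g%s\n",
              x$interaction$estimate, x$interaction$se, x$interaction$p,
              if (x$flagged) "  [flagged at 0.10]" else ""))
  invisible(x)
}

#' Descriptives by weight status
#'
#' Means and SDs of continuous variables and counts/percentages of
#' categorical variables within each weight-status group, with one-way ANOVA
#' (continuous) or chi-square (categorical) tests of group differences.
#'
#' @param demographics cleaned demographics with `weight_status`.
#' @param tfeq_scores TFEQ score table merged in by `participant_id` (may be
#'   `NULL`).
#' @param continuous,categorical variable names to summarize; defaults pick
#'   the usual study set from whatever is present.
#' @return A list with `continuous` (variable, per-group mean/sd, F, p) and
#'   `categorical` (variable, level, per-group n and percent, chi-square p).
#' @export
describe_by_weight_status <- function(demographics, tfeq_scores = NULL,
                                      continuous = NULL, categorical = NULL) {
  stopifnot("weight_status" %in% names(demographics))
  tab <- demographics
  if (!is.null(tfeq_scores))
    tab <- merge(tab, tfeq_scores, by = "participant_id")
  if (is.null(continuous))
    continuous <- intersect(c("age", "income", "bmi", "cr", "ue", "ee",
                              "disinhibited"), names(tab))
  if (is.null(categorical))
    categorical <- intersect(c("sex", "race", "education"), names(tab))

  groups <- levels(droplevels(factor(tab$weight_status)))
  empty <- setdiff(c("healthy", "overweight", "obese"), groups)
  if (length(empty))
    warning("weight-status group(s) with n = 0 omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)

  cont <- lapply(continuous, function(v) {
    row <- data.frame(variable = v)
    for (g in groups) {
      x <- tab[[v]][tab$weight_status == g]
      row[[paste0(g, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- stats::sd(x, na.rm = TRUE)
    }
    a <- stats::aov(tab[[v]] ~ factor(tab$weight_status))
    s <- summary(a)[[1]]
    row$F <- s[["F value"]][1]
    row$p <- s[["Pr(>F)"]][1]
    row
  })

  cat_rows <- lapply(categorical, function(v) {
    ct <- table(tab[[v]], factor(tab$weight_status, levels = groups))
    p <- tryCatch(suppressWarnings(stats::chisq.test(ct)$p.value),
                  error = function(e) NA_real_)
    lv <- rownames(ct)
    row <- data.frame(variable = v, level = lv)
    for (g in groups) {
      row[[paste0(g, "_n")]] <- as.integer(ct[, g])
      row[[paste0(g, "_pct")]] <- 100 * ct[, g] / sum(ct[, g])
    }
    row$p <- p
    row
  })

  list(continuous = do.call(rbind, cont),
       categorical = do.call(rbind, cat_rows))
}

#' Reaction-time effect over a difference-score span
#'
#' Converts a per-unit RT coefficient into the total speed difference across
#' a span of difference-score units (e.g. the full -4..4 single-attribute
#' span is 8 units), reported to the nearest millisecond.
#'
#' @param coefficient ms per difference-score unit.
#' @param span number of units spanned.
#' @return `|coefficient| * span`, rounded to the nearest ms.
#' @export
#' @examples
#' span_effect(-11.67, 8) # 93
span_effect <- function(coefficient, span) {
  if (!is.finite(coefficient) || !is.finite(span))
    stop("inputs must be finite", call. = FALSE)
  round(abs(coefficient) * span)
}
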