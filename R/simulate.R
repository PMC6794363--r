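#' Simulation configuration for a synthetic study cohort
#'
#' Bundles every parameter of the synthetic-cohort generator with validation.
#' Defaults emulate the study conditions: 500 adults, 50 rated foods, 49
#' preference trials against a referent, uncontrolled and emotional eating
#' correlated near 0.70, mean reaction times near 1.3 s with a 4 s stimulus
#' cap, and RT slopes of roughly -13 (health) and -12 (taste) ms per
#' difference-score unit.
#'
#' @param n_participants number of simulated participants.
#' @param n_foods number of food items rated (>= 3); each participant's
#'   trials pit the referent against the remaining `n_foods - 1` items.
#' @param seed integer RNG seed; the generator is bit-reproducible given
#'   `(config, seed)` and restores the caller's RNG state on exit.
#' @param rho_ue_ee target Pearson correlation between the scored
#'   uncontrolled-eating and emotional-eating subscales.
#' @param trait_means,trait_sds named numeric vectors (`cr`, `ue`, `ee`) on
#'   the 0-100 subscale scale.
#' @param trait_cr_corr latent correlation of cognitive restraint with each
#'   disinhibition trait.
#' @param ee_sex_shift additive shift of the emotional-eating mean for
#'   female participants (0-100 scale units).
#' @param food_health_taste_corr correlation of the foods' latent health and
#'   taste values.
#' @param rating_noise_sd SD of participant-level rating noise around each
#'   food's latent value, in rating units (ratings are then rounded and
#'   clipped to 1..5).
#' @param tfeq_item_noise_sd SD of item-level noise when a trait is
#'   discretized onto the questionnaire item scale, in item units.
#' @param gamma list of coefficients linking traits to preference weights:
#'   `w_health_base`, `w_taste_base`, and the per-SD modulations
#'   `cr_health`, `dis_health`, `cr_taste`, `dis_taste`. The health weight
#'   rises with cognitive restraint and falls with disinhibition; the taste
#'   weight does the reverse.
#' @param w_resid_sd SD of the idiosyncratic (trait-independent) component
#'   of each preference weight, utility units per rating unit. Most
#'   between-person variation in sensitivity is not trait-linked; this keeps
#'   the trait-to-sensitivity standardized slopes at a realistic magnitude
#'   while leaving the weights themselves well identified from 49 trials.
#' @param rt_slope_resid_sd SD of the idiosyncratic component of each
#'   participant's RT slopes, ms per difference unit.
#' @param preference_noise_sd SD of trial-level utility noise, in utility
#'   units. Utilities map to the -2..2 Likert preference through fixed
#'   symmetric thresholds at -1.5, -0.5, 0.5, 1.5.
#' @param rt_base_ms baseline reaction time, ms.
#' @param rt_slope_health_ms,rt_slope_taste_ms population-mean RT decrease
#'   per unit of the preferred-minus-non-preferred health/taste difference,
#'   ms per unit.
#' @param rt_trait_modulation per-SD trait modulation of the RT slopes, ms
#'   per unit: the health slope steepens with cognitive restraint and
#'   flattens with disinhibition, the taste slope the reverse. Set to 0 for
#'   a no-moderation (null) generator.
#' @param rt_age_slope_ms RT increase per year of age above the sample
#'   centre, ms (gives covariate screening a real signal to find).
#' @param rt_noise_sigma SD of multiplicative lognormal RT noise on the log
#'   scale (RTs are positive and right-skewed).
#' @param outlier_rate fraction of trials receiving an inflated RT.
#' @param outlier_scale length-2 range of the multiplicative inflation for
#'   outlier trials.
#' @param rt_cap_ms stimulus presentation cap, ms; RTs are clipped to
#'   `[rt_floor_ms, rt_cap_ms]` and recorded to the nearest millisecond.
#' @param rt_floor_ms smallest producible RT, ms.
#' @param bmi_cr_coef kg/m^2 shift in BMI per SD of cognitive restraint
#'   (higher restraint in heavier participants).
#' @param item_map questionnaire item map, see [tfeq_item_map()].
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 500L, n_foods = 50L, seed = 1L,
                       rho_ue_ee = 0.70,
                       trait_means = c(cr = 42, ue = 36, ee = 36),
                       trait_sds = c(cr = 22, ue = 19, ee = 28),
                       trait_cr_corr = 0.15,
                       ee_sex_shift = 4,
                       food_health_taste_corr = -0.3,
                       rating_noise_sd = 0.5,
                       tfeq_item_noise_sd = 0.3,
                       gamma = list(w_health_base = 0.35, w_taste_base = 0.65,
                                    cr_health = 0.15, dis_health = 0.10,
                                    cr_taste = 0.10, dis_taste = 0.15),
                       w_resid_sd = 0.4,
                       preference_noise_sd = 0.5,
                       rt_base_ms = 1300,
                       rt_slope_health_ms = 13,
                       rt_slope_taste_ms = 12,
                       rt_trait_modulation = 6,
                       rt_slope_resid_sd = 2,
                       rt_age_slope_ms = 6,
                       rt_noise_sigma = 0.12,
                       outlier_rate = 0.02,
                       outlier_scale = c(1.8, 3),
                       rt_cap_ms = 4000,
                       rt_floor_ms = 200,
                       bmi_cr_coef = 1.8,
                       item_map = tfeq_item_map()) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_foods = as.integer(n_foods),
    seed = as.integer(seed), rho_ue_ee = rho_ue_ee,
    trait_means = trait_means, trait_sds = trait_sds,
    trait_cr_corr = trait_cr_corr, ee_sex_shift = ee_sex_shift,
    food_health_taste_corr = food_health_taste_corr,
    rating_noise_sd = rating_noise_sd,
    tfeq_item_noise_sd = tfeq_item_noise_sd,
    gamma = gamma, w_resid_sd = w_resid_sd,
    preference_noise_sd = preference_noise_sd,
    rt_base_ms = rt_base_ms, rt_slope_health_ms = rt_slope_health_ms,
    rt_slope_taste_ms = rt_slope_taste_ms,
    rt_trait_modulation = rt_trait_modulation,
    rt_slope_resid_sd = rt_slope_resid_sd,
    rt_age_slope_ms = rt_age_slope_ms, rt_noise_sigma = rt_noise_sigma,
    outlier_rate = outlier_rate, outlier_scale = outlier_scale,
    rt_cap_ms = rt_cap_ms, rt_floor_ms = rt_floor_ms,
    bmi_cr_coef = bmi_cr_coef, item_map = item_map
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c("rho_ue_ee", "trait_means", "trait_sds", "trait_cr_corr",
                  "ee_sex_shift", "food_health_taste_corr", "rating_noise_sd",
                  "tfeq_item_noise_sd", "w_resid_sd", "preference_noise_sd",
                  "rt_base_ms", "rt_slope_health_ms", "rt_slope_taste_ms",
                  "rt_trait_modulation", "rt_slope_resid_sd",
                  "rt_age_slope_ms", "rt_noise_sigma",
                  "outlier_rate", "outlier_scale", "rt_cap_ms", "rt_floor_ms",
                  "bmi_cr_coef")
  for (f in num_fields) {
    if (any(!is.finite(cfg[[f]])))
      stop("non-finite value in config field '", f, "'", call. = FALSE)
  }
  if (any(!is.finite(unlist(cfg$gamma))))
    stop("non-finite gamma coefficient", call. = FALSE)
  if (cfg$n_participants < 1L) stop("n_participants must be positive", call. = FALSE)
  if (cfg$n_foods < 3L) stop("n_foods must be at least 3", call. = FALSE)
  for (f in c("trait_sds", "rating_noise_sd", "tfeq_item_noise_sd",
              "w_resid_sd", "preference_noise_sd", "rt_slope_resid_sd",
              "rt_noise_sigma"))
    if (any(cfg[[f]] < 0)) stop("'", f, "' must be nonnegative", call. = FALSE)
  for (f in c("rho_ue_ee", "trait_cr_corr", "food_health_taste_corr"))
    if (abs(cfg[[f]]) > 1) stop("'", f, "' must lie in [-1, 1]", call. = FALSE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$rt_cap_ms <= cfg$rt_base_ms)
    stop("rt_cap_ms must exceed rt_base_ms", call. = FALSE)
  if (!setequal(names(cfg$trait_means), c("cr", "ue", "ee")) ||
      !setequal(names(cfg$trait_sds), c("cr", "ue", "ee")))
    stop("trait_means and trait_sds need names cr, ue, ee", call. = FALSE)
  validate_item_map(cfg$item_map)
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Any subset of [sim_config()]'s arguments may appear in the file; the rest
#' keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(sim_config)), "item_map")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in c("trait_means", "trait_sds")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  if (!is.null(vals$gamma)) vals$gamma <- as.list(vals$gamma)
  if (!is.null(vals$outlier_scale)) vals$outlier_scale <- unlist(vals$outlier_scale)
  do.call(sim_config, vals)
}

# Expected attenuation of a trait correlation induced by item-level noise,
# rounding, and averaging over k items: used to pre-compensate the latent
# UE-EE correlation so the *scored* subscales hit the configured target.
# The closing constant is an empirical allowance for item floor/ceiling
# censoring (traits near the scale ends pin their items at the range
# limits), calibrated once at the default trait distributions.
tfeq_censoring_adjust <- 0.975

tfeq_attenuation <- function(cfg) {
  map <- cfg$item_map
  rel <- function(sub) {
    rows <- map[map$subscale == sub, , drop = FALSE]
    k <- nrow(rows)
    r <- mean(rows$max - rows$min)
    err_item <- cfg$tfeq_item_noise_sd^2 + 1 / 12  # noise + rounding, item units
    err_score <- err_item * 10000 / (k * r^2)      # on the 0-100 scale
    s2 <- cfg$trait_sds[[sub]]^2
    s2 / (s2 + err_score)
  }
  sqrt(rel("ue") * rel("ee")) * tfeq_censoring_adjust
}

with_preserved_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rmvnorm3 <- function(n, means, Sigma) {
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(n * 3L), n, 3L)
  sweep(z %*% L, 2L, means, `+`)
}

#' Generate a complete synthetic study cohort
#'
#' Draws participant traits (cognitive restraint, uncontrolled eating,
#' emotional eating) from a trivariate normal whose latent UE-EE correlation
#' is pre-compensated for item-noise attenuation; discretizes traits onto the
#' 18 questionnaire items; draws latent food health/taste values with the
#' configured (negative) correlation and per-participant noisy 1-5 ratings;
#' selects each participant's referent by the scoring rule itself; generates
#' -2..2 preferences from the utility
#' `u = w_health * dhealth + w_taste * dtaste + noise` through fixed
#' thresholds; and generates reaction times from the linear difference-score
#' model `rt = base + age effect - b_health * health_diff -
#' b_taste * taste_diff`, with multiplicative lognormal noise, a configurable
#' fraction of inflated outlier trials, clipping to the stimulus window and
#' millisecond rounding.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"diet_cohort"` with elements `demographics`,
#'   `tfeq_items`, `ratings`, `trials`, `ground_truth` (the latent traits,
#'   preference weights and RT slopes the pipeline tries to recover; never
#'   read by the scoring code), and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 20, seed = 7))
#' str(cohort$trials)
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_preserved_rng(config$seed, {
    n <- config$n_participants
    nf <- config$n_foods
    ids <- sprintf("P%04d", seq_len(n))

    ## --- demographics -------------------------------------------------
    sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
    age <- round(pmin(pmax(stats::rnorm(n, 33.6, 7.9), 18), 50))
    race <- sample(c("white", "african_american", "other"), n, replace = TRUE,
                   prob = c(0.83, 0.07, 0.10))
    education <- sample(c("high_school", "some_college", "bachelor", "graduate"),
                        n, replace = TRUE, prob = c(0.2, 0.3, 0.35, 0.15))
    income <- round(pmin(pmax(exp(stats::rnorm(n, log(42000), 0.6)), 5000), 250000))

    ## --- traits -------------------------------------------------------
    mu <- config$trait_means
    sds <- config$trait_sds
    rho_lat <- min(0.98, config$rho_ue_ee / tfeq_attenuation(config))
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- R[1, 3] <- R[3, 1] <- config$trait_cr_corr
    R[2, 3] <- R[3, 2] <- rho_lat
    Sigma <- diag(sds[c("cr", "ue", "ee")]) %*% R %*% diag(sds[c("cr", "ue", "ee")])
    traits <- rmvnorm3(n, c(mu[["cr"]], mu[["ue"]], mu[["ee"]]), Sigma)
    cr <- traits[, 1]
    ue <- traits[, 2]
    ee <- traits[, 3] + ifelse(sex == "female", config$ee_sex_shift, 0)

    zcr <- (cr - mu[["cr"]]) / sds[["cr"]]
    dis <- (ue + ee) / 2
    sd_dis <- sqrt(sds[["ue"]]^2 + sds[["ee"]]^2 +
                   2 * rho_lat * sds[["ue"]] * sds[["ee"]]) / 2
    zdis <- (dis - (mu[["ue"]] + mu[["ee"]]) / 2) / sd_dis

    ## body size: restraint runs higher in heavier participants
    bmi <- pmin(pmax(26.5 + config$bmi_cr_coef * zcr + stats::rnorm(n, 0, 5.5),
                     16), 55)
    height <- pmin(pmax(stats::rnorm(n, ifelse(sex == "male", 1.77, 1.63),
                                     0.07), 1.45), 2.10)
    weight <- round(bmi * height^2, 1)
    height <- round(height, 3)

    demographics <- data.frame(
      participant_id = ids, age = age, sex = sex, height_m = height,
      weight_kg = weight, race = race, income = income, education = education
    )

    ## --- TFEQ item responses -------------------------------------------
    map <- config$item_map
    items <- matrix(NA_integer_, n, 18L)
    trait_of <- cbind(cr = cr, ue = ue, ee = ee)
    for (j in seq_len(18L)) {
      row <- map[map$item == j, ]
      t <- trait_of[, row$subscale]
      latent <- row$min + (row$max - row$min) * t / 100 +
        stats::rnorm(n, 0, config$tfeq_item_noise_sd)
      resp <- pmin(pmax(round(latent), row$min), row$max)
      if (row$reverse) resp <- row$min + row$max - resp
      items[, j] <- as.integer(resp)
    }
    tfeq_items <- data.frame(participant_id = ids, items)
    names(tfeq_items)[-1L] <- paste0("tfeq_", seq_len(18L))

    ## --- food ratings ---------------------------------------------------
    fr <- config$food_health_taste_corr
    Lf <- chol(matrix(c(1, fr, fr, 1), 2))
    zf <- matrix(stats::rnorm(nf * 2L), nf, 2L) %*% Lf
    food_health <- 3 + zf[, 1]
    food_taste <- 3 + zf[, 2]

    rate <- function(latent) {
      m <- matrix(rep(latent, each = n), n, nf) +
        stats::rnorm(n * nf, 0, config$rating_noise_sd)
      matrix(as.integer(pmin(pmax(round(m), 1L), 5L)), n, nf)
    }
    health_m <- rate(food_health)
    taste_m <- rate(food_taste)
    ratings <- data.frame(
      participant_id = rep(ids, times = nf),
      item_id = rep(seq_len(nf), each = n),
      taste = as.vector(taste_m),
      health = as.vector(health_m)
    )
    ratings <- ratings[order(ratings$participant_id, ratings$item_id), ]
    rownames(ratings) <- NULL

    ## --- preference weights and RT slopes (ground truth) ----------------
    g <- config$gamma
    w_health <- g$w_health_base + g$cr_health * zcr - g$dis_health * zdis +
      stats::rnorm(n, 0, config$w_resid_sd)
    w_taste <- g$w_taste_base - g$cr_taste * zcr + g$dis_taste * zdis +
      stats::rnorm(n, 0, config$w_resid_sd)
    m_mod <- config$rt_trait_modulation
    b_health <- config$rt_slope_health_ms + m_mod * zcr - m_mod * zdis +
      stats::rnorm(n, 0, config$rt_slope_resid_sd)
    b_taste <- config$rt_slope_taste_ms - m_mod * zcr + m_mod * zdis +
      stats::rnorm(n, 0, config$rt_slope_resid_sd)

    ## --- trials ---------------------------------------------------------
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      rti <- data.frame(item_id = seq_len(nf), taste = taste_m[i, ],
                        health = health_m[i, ])
      ref <- select_referent(rti)
      targets <- sample(setdiff(seq_len(nf), ref))
      dh <- health_m[i, targets] - health_m[i, ref]
      dt <- taste_m[i, targets] - taste_m[i, ref]
      u <- w_health[i] * dh + w_taste[i] * dt +
        stats::rnorm(length(targets), 0, config$preference_noise_sd)
      pref <- as.integer(as.character(
        cut(u, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf), labels = -2:2)))
      ## preferred-minus-non-preferred differences drive RT; 0 when neutral
      hd <- ifelse(pref == 0, 0, sign(pref) * dh)
      td <- ifelse(pref == 0, 0, sign(pref) * dt)
      det <- config$rt_base_ms + config$rt_age_slope_ms * (age[i] - 34) -
        b_health[i] * hd - b_taste[i] * td
      rt <- det * exp(stats::rnorm(length(det), 0, config$rt_noise_sigma))
      out <- stats::runif(length(rt)) < config$outlier_rate
      if (any(out))
        rt[out] <- rt[out] * stats::runif(sum(out), config$outlier_scale[1],
                                          config$outlier_scale[2])
      rt <- round(pmin(pmax(rt, config$rt_floor_ms), config$rt_cap_ms))
      trials[[i]] <- data.frame(
        participant_id = ids[i], trial_index = seq_along(targets),
        target_item_id = targets, referent_item_id = ref,
        preference = pref, rt_ms = rt
      )
    }
    trials <- do.call(rbind, trials)
    rownames(trials) <- NULL

    ground_truth <- data.frame(
      participant_id = ids, cr_true = cr, ue_true = ue, ee_true = ee,
      w_health = w_health, w_taste = w_taste,
      b_health_ms = b_health, b_taste_ms = b_taste
    )

    structure(list(demographics = demographics, tfeq_items = tfeq_items,
                   ratings = ratings, trials = trials,
                   ground_truth = ground_truth, config = config),
              class = "diet_cohort")
  })
}

#' @export
print.diet_cohort <- function(x, ...) {
  cat("Synthetic dietary decision-making cohort\n")
  cat("  participants:", nrow(x$demographics),
      " foods:", x$config$n_foods,
      " trials:", nrow(x$trials), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a cohort's tables as tab-separated text
#'
#' Writes `demographics.tsv`, `tfeq_items.tsv`, `ratings.tsv`, `trials.tsv`,
#' `ground_truth.tsv` and a `manifest.yaml` recording the seed, key config
#' values and per-table row counts. The ground truth is written separately
#' and is never read back by the scoring pipeline.
#'
#' @param cohort a `diet_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "diet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("demographics", "tfeq_items", "ratings", "trials", "ground_truth")
  for (tb in tabs)
    utils::write.table(cohort[[tb]], file.path(dir, paste0(tb, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    n_participants = cohort$config$n_participants,
    n_foods = cohort$config$n_foods,
    rows = lapply(stats::setNames(tabs, tabs),
                  function(tb) nrow(cohort[[tb]]))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing the `.tsv` tables.
#' @param ground_truth read `ground_truth.tsv` too (only available for
#'   synthetic cohorts; the scoring pipeline never uses it).
#' @return A list with `demographics`, `tfeq_items`, `ratings`, `trials`
#'   (and `ground_truth` when requested).
#' @export
read_cohort <- function(dir, ground_truth = FALSE) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  out <- list(demographics = rd("demographics"), tfeq_items = rd("tfeq_items"),
              ratings = rd("ratings"), trials = rd("trials"))
  if (ground_truth) out$ground_truth <- rd("ground_truth")
  out
}
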