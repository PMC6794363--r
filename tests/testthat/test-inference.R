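test_that("BMI, weight status and the plausibility screen follow the rules", {
  expect_identical(as.character(assign_weight_status(c(24.9, 25, 29.9, 30))),
                   c("healthy", "overweight", "overweight", "obese"))

  dem <- data.frame(participant_id = c("A", "B"),
                    height_m = c(1.75, 1.60), weight_kg = c(70, 60))
  tr <- rbind(make_trials(2:4, 1L, c(1L, -1L, 0L), pid = "A"),
              make_trials(2:4, 1L, c(2L, 1L, -2L), pid = "B"))
  out <- clean_participants(dem, tr)
  expect_identical(nrow(out$demographics), 2L)
  expect_equal(out$demographics$bmi[1], 70 / 1.75^2)
  expect_identical(as.character(out$demographics$weight_status[1]), "healthy")
})

test_that("a 522-person cohort with five rule violators retains 517", {
  co <- generate_cohort(sim_config(n_participants = 522, seed = 17))
  dem <- co$demographics
  trials <- co$trials
  ratings <- co$ratings
  # three implausibly short participants, one implausible BMI
  dem$height_m[1:3] <- 0.5
  dem$weight_kg[4] <- round(3 * dem$height_m[4]^2, 1)
  # one invariant responder: same answer on every task question
  p5 <- dem$participant_id[5]
  trials$preference[trials$participant_id == p5] <- 2L
  ratings$taste[ratings$participant_id == p5] <- 3L
  ratings$health[ratings$participant_id == p5] <- 3L

  out <- clean_participants(dem, trials, ratings)
  expect_identical(nrow(out$demographics), 517L)
  expect_identical(nrow(out$exclusions), 5L)
  counts <- table(out$exclusions$rule)
  expect_identical(unname(counts[["implausible_height"]]), 3L)
  expect_identical(unname(counts[["implausible_bmi"]]), 1L)
  expect_identical(unname(counts[["invariant_responder"]]), 1L)
  # every dropped participant appears on exactly one report line
  expect_identical(anyDuplicated(out$exclusions$participant_id), 0L)
})

test_that("covariate screening keys on the p < 0.10 correlation rule", {
  set.seed(31)
  n <- 300
  outc <- data.frame(participant_id = sprintf("P%03d", 1:n), y = rnorm(n))
  dem <- data.frame(participant_id = outc$participant_id,
                    mirror = outc$y,                    # identical -> in
                    noise = rnorm(n),                   # independent
                    flat = 1)                           # constant -> warning
  expect_warning(sc <- screen_covariates(dem, outc), "constant")
  expect_true("mirror" %in% sc$covariates)
  expect_lt(sc$table$p[sc$table$demographic == "mirror"], 1e-10)

  # independent demographics enter at about the nominal rate
  hits <- sapply(1:150, function(i) {
    d <- data.frame(participant_id = outc$participant_id, x = rnorm(n))
    length(screen_covariates(d, outc)$covariates) > 0
  })
  expect_gt(mean(hits), 0.04)
  expect_lt(mean(hits), 0.18)

  # the generator's built-in age -> RT dependence is found
  co <- default_cohort_scored()
  rt_mean <- aggregate(list(mean_rt_ms = co$cohort$trials$rt_ms),
                       by = list(participant_id = co$cohort$trials$participant_id),
                       mean)
  sc2 <- screen_covariates(co$cleaned$demographics, rt_mean,
                           vars = c("age", "race"))
  expect_true("age" %in% sc2$covariates)
})

test_that("categoricals are indicator-coded against the modal level", {
  dem <- data.frame(participant_id = c("A", "B", "C", "D"),
                    race = c("w", "w", "b", "o"))
  outc <- data.frame(participant_id = dem$participant_id, y = c(1, 2, 3, 4))
  sc <- screen_covariates(dem, outc)
  expect_setequal(unique(sc$table$demographic), c("race.b", "race.o"))
  expect_match(sc$coding$race, "reference 'w'")
})

test_that("model results carry exact t-based confidence intervals", {
  set.seed(41)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  fit <- lm(y ~ x, data = d)
  mr <- model_result(fit, "toy")
  ci <- confint(fit)
  expect_equal(mr$ci_lo, unname(ci[, 1]))
  expect_equal(mr$ci_hi, unname(ci[, 2]))
  expect_true(all(mr$p >= 0 & mr$p <= 1))
})

test_that("standardized simple slopes recover built-in effects", {
  set.seed(43)
  n <- 400
  cr <- rnorm(n, 40, 20)
  dis <- rnorm(n, 35, 18)
  tab <- data.frame(
    participant_id = sprintf("P%03d", 1:n), cr = cr, disinhibited = dis,
    health_sensitivity = 0.5 * scale(cr)[, 1] + rnorm(n, 0, sqrt(0.75)),
    taste_sensitivity = rnorm(n),
    prop_healthy = pmin(pmax(0.5 + 0.1 * scale(cr)[, 1] + rnorm(n, 0, 0.1),
                             0), 1),
    prop_tasty = runif(n)
  )
  om <- fit_outcome_models(tab)
  b <- function(model, term) om$estimate[om$model == model & om$term == term]
  expect_equal(b("health_sensitivity ~ cr (unadjusted)", "cr"), 0.5,
               tolerance = 0.15)
  # standardized simple slope IS the Pearson correlation
  expect_equal(b("taste_sensitivity ~ disinhibited (unadjusted)",
                 "disinhibited"),
               cor(tab$taste_sensitivity, dis), tolerance = 1e-12)
  # a null outcome stays within sampling error of zero
  expect_lt(abs(b("taste_sensitivity ~ cr (unadjusted)", "cr")), 0.15)
})

test_that("trial-level RT models recover homogeneous generator slopes", {
  cfg <- sim_config(n_participants = 120, seed = 23, rt_trait_modulation = 0,
                    rt_slope_resid_sd = 0)
  co <- generate_cohort(cfg)
  sc <- score_tfeq(co$tfeq_items)
  task <- suppressMessages(score_task(co$ratings, co$trials))
  rtm <- fit_rt_models(task$derived, sc)
  joint <- rtm[rtm$model == "rt_ms ~ health_diff + taste_diff (adjusted)", ]
  hrow <- joint[joint$term == "health_diff", ]
  # the -13 ms/unit generating slope lies inside the fitted CI
  expect_lt(hrow$ci_lo, -13)
  expect_gt(hrow$ci_hi, -13)

  # with the RT slopes switched off entirely, estimates hover near zero
  cfg0 <- sim_config(n_participants = 120, seed = 24, rt_trait_modulation = 0,
                     rt_slope_resid_sd = 0, rt_slope_health_ms = 0,
                     rt_slope_taste_ms = 0)
  co0 <- generate_cohort(cfg0)
  task0 <- suppressMessages(score_task(co0$ratings, co0$trials))
  rtm0 <- fit_rt_models(task0$derived, score_tfeq(co0$tfeq_items))
  j0 <- rtm0[rtm0$model == "rt_ms ~ health_diff + taste_diff (adjusted)", ]
  expect_true(all(abs(j0$estimate[j0$term != "(Intercept)"]) <
                    3.5 * j0$se[j0$term != "(Intercept)"]))

  # cluster-robust SEs never pretend to more precision on the trait terms
  rtmc <- fit_rt_models(task$derived, sc, cluster_robust = TRUE)
  crow <- function(m, t, tab) tab$se[tab$model == m & tab$term == t]
  expect_gt(crow("rt_ms ~ cr (unadjusted)", "cr", rtmc),
            0.5 * crow("rt_ms ~ cr (unadjusted)", "cr", rtm))
})

test_that("median-split ties go low; binary moderator matches continuous form", {
  set.seed(61)
  n <- 40
  ids <- sprintf("P%02d", 1:n)
  scores <- data.frame(participant_id = ids,
                       cr = rep(c(20, 60), each = n / 2),
                       disinhibited = rnorm(n, 40, 10))
  derived <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- 30
    hd <- sample(-4:4, k, TRUE)
    data.frame(participant_id = ids[i], target_item_id = seq_len(k) + 1,
               referent_item_id = 1L, preference = 1L,
               rt_ms = 1300 - 10 * hd + rnorm(k, 0, 120),
               preferred_side = "target", health_diff = hd,
               taste_diff = sample(-4:4, k, TRUE),
               ht_diff_raw = 0L, ht_diff = 0L, rt_retained = TRUE)
  }))
  med <- moderation_analysis(derived, scores, "cr", "health", "median")
  cont <- moderation_analysis(derived, scores, "cr", "health", "continuous")
  # binary moderator: split and z-scored forms are affine-equivalent
  expect_equal(med$interaction$p, cont$interaction$p, tolerance = 1e-9)
  expect_equal(med$interaction$t, cont$interaction$t, tolerance = 1e-6)

  # participants at the median fall in the low stratum
  scores3 <- data.frame(participant_id = ids[1:3],
                        cr = c(10, 20, 30), disinhibited = 40)
  der3 <- derived[derived$participant_id %in% ids[1:3], ]
  m3 <- moderation_analysis(der3, scores3, "cr", "health", "median")
  expect_identical(m3$strata$low$n_obs[1], sum(der3$participant_id %in%
                                                 ids[1:2]))

  expect_error(moderation_analysis(
    derived[derived$participant_id == ids[1], ], scores[1, ],
    "cr", "health", "median"), "empty stratum")
})

test_that("weight-status descriptives reduce to the two-sample t test", {
  set.seed(71)
  dem <- data.frame(participant_id = sprintf("P%03d", 1:200),
                    weight_status = rep(c("healthy", "obese"), each = 100),
                    age = c(rnorm(100, 0), rnorm(100, 1)))
  expect_warning(
    ds <- describe_by_weight_status(dem, NULL, continuous = "age",
                                    categorical = character(0)),
    "n = 0 omitted")
  tt <- t.test(age ~ weight_status, data = dem, var.equal = TRUE)
  expect_equal(ds$continuous$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_lt(ds$continuous$p, 0.001)

  # identical group distributions: no significance to find
  dem$age <- rnorm(200)
  expect_warning(
    ds2 <- describe_by_weight_status(dem, NULL, continuous = "age",
                                     categorical = character(0)),
    "n = 0 omitted")
  expect_gt(ds2$continuous$p, 0.01)
})

test_that("span conversion turns per-unit slopes into millisecond effects", {
  expect_identical(span_effect(0, 8), 0)
  expect_identical(span_effect(-10, 4), 40)
  expect_error(span_effect(Inf, 4), "finite")
})
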