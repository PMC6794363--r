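#' Select the referent food for one participant
#'
#' The referent is the rated item closest to the participant's median taste
#' and median health rating, minimizing the Euclidean distance from
#' `(taste, health)` to `(median taste, median health)` (Chebyshev distance
#' available as an option). Ties are broken by the lowest item id, so the
#' choice is deterministic.
#'
#' @param ratings data.frame for one participant with columns `item_id`,
#'   `taste`, `health` (integer 1-5), one row per item.
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return The selected `item_id`.
#' @export
#' @examples
#' r <- data.frame(item_id = 1:3, taste = c(1, 3, 5), health = c(1, 3, 5))
#' select_referent(r) # 2
select_referent <- function(ratings, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  validate_ratings(ratings)
  if (nrow(ratings) < 3L)
    stop("need at least 3 rated items to pick a referent", call. = FALSE)
  med_t <- stats::median(ratings$taste)
  med_h <- stats::median(ratings$health)
  dt <- ratings$taste - med_t
  dh <- ratings$health - med_h
  d <- switch(metric,
    euclidean = sqrt(dt^2 + dh^2),
    chebyshev = pmax(abs(dt), abs(dh))
  )
  ord <- order(d, ratings$item_id)
  ratings$item_id[ord[1L]]
}

validate_ratings <- function(ratings) {
  stopifnot(is.data.frame(ratings),
            all(c("item_id", "taste", "health") %in% names(ratings)))
  bad <- function(x) any(!is.finite(x) | x < 1 | x > 5 | x != round(x))
  if (bad(ratings$taste) || bad(ratings$health))
    stop("ratings must be integers in 1..5", call. = FALSE)
  if (anyDuplicated(ratings[c("item_id",
                              if ("participant_id" %in% names(ratings)) "participant_id")]))
    stop("duplicate (participant, item) rating", call. = FALSE)
  invisible(ratings)
}

#' Collapse extreme health-taste difference scores
#'
#' The composite health-minus-taste difference score spans -8..8; the sparse
#' extremes are recoded so that \{-8, -7, -6\} become -5 and \{6, 7, 8\}
#' become 5, leaving -5..5. The map is idempotent and order preserving.
#'
#' @param x integer vector in -8..8.
#' @return Integer vector in -5..5.
#' @export
collapse_ht <- function(x) {
  if (any(abs(x[!is.na(x)]) > 8))
    stop("health-taste difference outside -8..8", call. = FALSE)
  pmax(pmin(x, 5L), -5L)
}

#' Derive trial-level difference scores
#'
#' For each preference trial, labels the preferred side (target when the
#' Likert preference is positive, referent when negative, none when neutral)
#' and, on trials where a preference was indicated, computes
#' \describe{
#'   \item{health_diff}{preferred food's health rating minus the non-preferred
#'     food's health rating (-4..4)}
#'   \item{taste_diff}{same for taste}
#'   \item{ht_diff_raw}{health_diff - taste_diff (-8..8)}
#'   \item{ht_diff}{ht_diff_raw with the extremes collapsed to -5..5}
#' }
#' Difference scores are `NA` on neutral trials: they are defined only when a
#' preference was indicated.
#'
#' @param trials data.frame with columns `participant_id`, `target_item_id`,
#'   `referent_item_id`, `preference` (integer -2..2), `rt_ms`.
#' @param ratings data.frame with columns `participant_id`, `item_id`,
#'   `taste`, `health` covering every item appearing in `trials`.
#' @return `trials` with columns `preferred_side`, `health_diff`,
#'   `taste_diff`, `ht_diff_raw`, `ht_diff` appended.
#' @export
derive_trials <- function(trials, ratings) {
  validate_trials(trials)
  validate_ratings(ratings)
  key <- function(pid, iid) paste(pid, iid, sep = "\r")
  idx <- match(key(trials$participant_id, trials$target_item_id),
               key(ratings$participant_id, ratings$item_id))
  jdx <- match(key(trials$participant_id, trials$referent_item_id),
               key(ratings$participant_id, ratings$item_id))
  if (anyNA(idx) || anyNA(jdx)) {
    miss <- which(is.na(idx) | is.na(jdx))[1L]
    stop("trial ", miss, " (participant ", trials$participant_id[miss],
         ") references an unrated item", call. = FALSE)
  }
  t_h <- ratings$health[idx]; t_t <- ratings$taste[idx]
  r_h <- ratings$health[jdx]; r_t <- ratings$taste[jdx]

  side <- ifelse(trials$preference > 0, "target",
                 ifelse(trials$preference < 0, "referent", "none"))
  sgn <- sign(trials$preference)
  hd <- ifelse(sgn == 0, NA_integer_, sgn * (t_h - r_h))
  td <- ifelse(sgn == 0, NA_integer_, sgn * (t_t - r_t))
  out <- trials
  out$preferred_side <- side
  out$health_diff <- as.integer(hd)
  out$taste_diff <- as.integer(td)
  out$ht_diff_raw <- as.integer(hd - td)
  out$ht_diff <- as.integer(collapse_ht(out$ht_diff_raw))
  out
}

validate_trials <- function(trials) {
  need <- c("participant_id", "target_item_id", "referent_item_id",
            "preference", "rt_ms")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  if (any(trials$target_item_id == trials$referent_item_id))
    stop("target and referent must differ", call. = FALSE)
  p <- trials$preference
  if (any(!is.finite(p) | p < -2 | p > 2 | p != round(p)))
    stop("preference must be an integer in -2..2", call. = FALSE)
  if (any(!is.finite(trials$rt_ms) | trials$rt_ms <= 0))
    stop("rt_ms must be positive", call. = FALSE)
  invisible(trials)
}

#' Per-participant health and taste sensitivity coefficients
#'
#' Fits, for one participant, the ordinary least squares model
#' `preference ~ 1 + (target health - referent health) +
#' (target taste - referent taste)` over all completed trials, neutral trials
#' included (preference 0 is a valid point on the -2..2 scale). The two slope
#' coefficients are the participant's health sensitivity and taste
#' sensitivity.
#'
#' @param trials trials data.frame for one participant (see [derive_trials()]).
#' @param ratings that participant's ratings.
#' @return A list with `health_sensitivity`, `taste_sensitivity`,
#'   `intercept`, `n_trials`, and `ok` (`FALSE` when the design is rank
#'   deficient, in which case the sensitivities are `NA`).
#' @export
estimate_sensitivities <- function(trials, ratings) {
  validate_trials(trials)
  if (nrow(trials) < 3L)
    stop("need at least 3 trials to estimate sensitivities", call. = FALSE)
  key <- function(iid) match(iid, ratings$item_id)
  ti <- key(trials$target_item_id); ri <- key(trials$referent_item_id)
  if (anyNA(ti) || anyNA(ri)) stop("trial references an unrated item", call. = FALSE)
  dh <- ratings$health[ti] - ratings$health[ri]
  dt <- ratings$taste[ti] - ratings$taste[ri]
  X <- cbind(1, dh, dt)
  qx <- qr(X)
  if (qx$rank < 3L) {
    return(list(health_sensitivity = NA_real_, taste_sensitivity = NA_real_,
                intercept = NA_real_, n_trials = nrow(trials), ok = FALSE))
  }
  beta <- qr.coef(qx, trials$preference)
  list(health_sensitivity = unname(beta[2L]),
       taste_sensitivity = unname(beta[3L]),
       intercept = unname(beta[1L]),
       n_trials = nrow(trials), ok = TRUE)
}

#' Proportions of healthy and tasty options preferred
#'
#' The proportion of healthy options preferred is the number of trials whose
#' health difference score exceeds zero divided by all completed trials
#' (neutral trials count in the denominator only, since difference scores are
#' undefined there); analogously for taste.
#'
#' @param derived derived trials for one participant, from [derive_trials()].
#' @return A list with `prop_healthy`, `prop_tasty`, `n_trials_completed`,
#'   `n_trials_preferred`.
#' @export
preference_proportions <- function(derived) {
  n <- nrow(derived)
  if (n < 1L) stop("no completed trials", call. = FALSE)
  pref <- derived$preferred_side != "none"
  list(
    prop_healthy = sum(derived$health_diff > 0, na.rm = TRUE) / n,
    prop_tasty = sum(derived$taste_diff > 0, na.rm = TRUE) / n,
    n_trials_completed = n,
    n_trials_preferred = sum(pref)
  )
}

#' Trim reaction-time outliers
#'
#' Removes trials whose reaction time falls outside mean +/- k standard
#' deviations, computed in a single pass (not iterated) within the trimming
#' unit: per participant by default, or pooled across the sample. With zero
#' RT variance nothing is removed.
#'
#' @param trials trials data.frame with `participant_id` and `rt_ms`.
#' @param k SD multiplier; default 2.2.
#' @param unit `"participant"` (default) or `"pooled"`.
#' @return A list with `retained` (the surviving trials), `removed`, and
#'   `report` (per-participant counts of removed trials).
#' @export
filter_rt_outliers <- function(trials, k = 2.2,
                               unit = c("participant", "pooled")) {
  unit <- match.arg(unit)
  stopifnot(all(c("participant_id", "rt_ms") %in% names(trials)))
  groups <- if (unit == "participant") trials$participant_id else rep(1L, nrow(trials))
  keep <- rep(TRUE, nrow(trials))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 3L) next
    rt <- trials$rt_ms[sel]
    m <- mean(rt); s <- stats::sd(rt)
    if (!is.finite(s) || s == 0) next
    keep[sel] <- rt >= m - k * s & rt <= m + k * s
  }
  removed <- trials[!keep, , drop = FALSE]
  report <- if (nrow(removed)) {
    stats::aggregate(list(n_removed = removed$rt_ms),
                     by = list(participant_id = removed$participant_id), length)
  } else {
    data.frame(participant_id = character(0), n_removed = integer(0))
  }
  list(retained = trials[keep, , drop = FALSE], removed = removed,
       report = report)
}

#' Score the dietary decision-making task for a cohort
#'
#' Runs [derive_trials()], [estimate_sensitivities()] and
#' [preference_proportions()] per participant and [filter_rt_outliers()]
#' across the cohort, returning the per-participant outcome table, the
#' per-trial derived table (flagged for RT retention) and the removal report.
#'
#' @param ratings cohort ratings table.
#' @param trials cohort trials table.
#' @param rt_k,rt_unit passed to [filter_rt_outliers()].
#' @return A list with `outcomes` (one row per participant:
#'   `health_sensitivity`, `taste_sensitivity`, `prop_healthy`, `prop_tasty`,
#'   trial counts, `sensitivity_ok`), `derived` (per-trial, with
#'   `rt_retained` flag), and `rt_report`.
#' @export
score_task <- function(ratings, trials, rt_k = 2.2,
                       rt_unit = c("participant", "pooled")) {
  rt_unit <- match.arg(rt_unit)
  derived <- derive_trials(trials, ratings)
  trim <- filter_rt_outliers(derived, k = rt_k, unit = rt_unit)
  row_id <- do.call(paste, c(derived[c("participant_id", "target_item_id")], sep = "\r"))
  kept_id <- do.call(paste, c(trim$retained[c("participant_id", "target_item_id")], sep = "\r"))
  derived$rt_retained <- row_id %in% kept_id

  ids <- unique(derived$participant_id)
  outcomes <- vector("list", length(ids))
  n_flagged <- 0L
  for (i in seq_along(ids)) {
    pid <- ids[i]
    tr <- derived[derived$participant_id == pid, , drop = FALSE]
    ra <- ratings[ratings$participant_id == pid, , drop = FALSE]
    sens <- estimate_sensitivities(tr, ra)
    if (!sens$ok) n_flagged <- n_flagged + 1L
    prop <- preference_proportions(tr)
    outcomes[[i]] <- data.frame(
      participant_id = pid,
      health_sensitivity = sens$health_sensitivity,
      taste_sensitivity = sens$taste_sensitivity,
      prop_healthy = prop$prop_healthy,
      prop_tasty = prop$prop_tasty,
      n_trials_completed = prop$n_trials_completed,
      n_trials_preferred = prop$n_trials_preferred,
      n_rt_trials_retained = sum(tr$rt_retained),
      sensitivity_ok = sens$ok
    )
  }
  if (n_flagged > 0L)
    message(n_flagged, " participant(s) had rank-deficient sensitivity designs; ",
            "their coefficients are NA and excluded downstream")
  list(outcomes = do.call(rbind, outcomes), derived = derived,
       rt_report = trim$report)
}
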