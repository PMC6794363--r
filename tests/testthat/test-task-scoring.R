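test_that("referent selection minimizes distance to the rating medians", {
  # an item rated exactly at the medians wins outright
  r <- make_ratings(taste = c(1, 3, 5), health = c(1, 3, 5))
  expect_identical(select_referent(r), 2L)

  # brute-force enumeration oracle with the lowest-index tie rule
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    r <- make_ratings(taste = sample(1:5, n, TRUE),
                      health = sample(1:5, n, TRUE))
    d <- sqrt((r$taste - median(r$taste))^2 + (r$health - median(r$health))^2)
    expect_identical(select_referent(r),
                     r$item_id[which(d == min(d))[1]])
  }

  # duplicate of the median item at a higher index loses the tie
  r <- make_ratings(taste = c(1, 2, 3, 4, 5, 3), health = c(5, 4, 3, 2, 1, 3))
  expect_identical(select_referent(r), 3L)

  expect_error(select_referent(make_ratings(3, 3)[0, ]), "3 rated items")
  # Chebyshev option changes the metric, still deterministic
  expect_identical(
    select_referent(make_ratings(c(1, 3, 5), c(1, 3, 5)), metric = "chebyshev"),
    2L)
})

test_that("trial derivation computes preferred-minus-non-preferred scores", {
  r <- make_ratings(taste = c(1, 5, 4, 2), health = c(5, 1, 3, 4))
  # strong yes for a healthy-but-untasty target vs a tasty-but-unhealthy
  # referent: raw composite 8 collapses to 5
  tr <- make_trials(target = 1L, referent = 2L, preference = 2L)
  d <- derive_trials(tr, r)
  expect_identical(d$preferred_side, "target")
  expect_identical(d$health_diff, 4L)
  expect_identical(d$taste_diff, -4L)
  expect_identical(d$ht_diff_raw, 8L)
  expect_identical(d$ht_diff, 5L)

  # neutral trial: no preferred side, difference scores undefined
  d0 <- derive_trials(make_trials(1L, 2L, 0L), r)
  expect_identical(d0$preferred_side, "none")
  expect_true(is.na(d0$health_diff) && is.na(d0$taste_diff))

  # preference for the referent: differences taken from the referent's side
  r2 <- make_ratings(taste = c(4, 2), health = c(3, 4))
  d2 <- derive_trials(make_trials(1L, 2L, -1L), r2)
  expect_identical(d2$preferred_side, "referent")
  expect_identical(d2$health_diff, 1L)
  expect_identical(d2$taste_diff, -2L)
  expect_identical(d2$ht_diff_raw, 3L)
  expect_identical(d2$ht_diff, 3L)

  expect_error(derive_trials(make_trials(9L, 2L, 1L), r), "unrated item")
})

test_that("derivation is antisymmetric under target/referent swap", {
  set.seed(33)
  for (i in 1:40) {
    r <- make_ratings(taste = sample(1:5, 6, TRUE),
                      health = sample(1:5, 6, TRUE))
    pr <- sample(c(-2L, -1L, 1L, 2L), 1)
    a <- derive_trials(make_trials(1L, 2L, pr), r)
    b <- derive_trials(make_trials(2L, 1L, -pr), r)
    expect_identical(a$health_diff, b$health_diff)
    expect_identical(a$taste_diff, b$taste_diff)
    expect_identical(a$ht_diff, b$ht_diff)
  }
})

test_that("collapsing is the stated recode, idempotent and order-preserving", {
  raw <- -8:8
  expect_identical(collapse_ht(raw),
                   c(-5L, -5L, -5L, -5:5, 5L, 5L, 5L))
  expect_identical(collapse_ht(collapse_ht(raw)), collapse_ht(raw))
  expect_true(all(diff(collapse_ht(raw)) >= 0))
  expect_identical(collapse_ht(-5:5), -5:5)  # untouched inside the range
  expect_error(collapse_ht(9L), "-8..8")
})

test_that("single-attribute differences cannot leave -4..4", {
  # exhaustive over every rating pair and preference sign
  grid <- expand.grid(th = 1:5, rh = 1:5, tt = 1:5, rt = 1:5, p = c(-2L, 2L))
  grid <- grid[!(grid$th == grid$rh & grid$tt == grid$rt), ]
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    r <- make_ratings(taste = c(g$tt, g$rt), health = c(g$th, g$rh))
    d <- derive_trials(make_trials(1L, 2L, g$p), r)
    expect_true(abs(d$health_diff) <= 4)
    expect_true(abs(d$taste_diff) <= 4)
    expect_true(abs(d$ht_diff) <= 5)
  }
})

test_that("sensitivities reproduce hand-solved and degenerate designs", {
  # orthogonal design: referent (3,3); targets step health or taste by 1
  r <- make_ratings(taste = c(3, 3, 3, 4, 2), health = c(3, 4, 2, 3, 3))
  tr <- make_trials(target = c(2L, 3L, 4L, 5L), referent = 1L,
                    preference = c(2L, -2L, 1L, -1L))
  s <- estimate_sensitivities(tr, r)
  expect_true(s$ok)
  expect_equal(s$health_sensitivity, 2)
  expect_equal(s$taste_sensitivity, 1)

  # preference identical to the health difference, taste orthogonal
  tr2 <- make_trials(target = c(2L, 3L, 4L, 5L), referent = 1L,
                     preference = c(1L, -1L, 0L, 0L))
  s2 <- estimate_sensitivities(tr2, r)
  expect_equal(s2$health_sensitivity, 1)
  expect_equal(s2$taste_sensitivity, 0)

  # constant zero outcome
  s3 <- estimate_sensitivities(make_trials(c(2L, 3L, 4L), 1L, c(0L, 0L, 0L)), r)
  expect_equal(s3$health_sensitivity, 0)
  expect_equal(s3$taste_sensitivity, 0)

  # collinear design flagged, not fitted
  rc <- make_ratings(taste = c(3, 4, 5, 2), health = c(3, 4, 5, 2))
  sc <- estimate_sensitivities(make_trials(c(2L, 3L, 4L), 1L, c(1L, 1L, -1L)), rc)
  expect_false(sc$ok)
  expect_true(is.na(sc$health_sensitivity))

  expect_error(estimate_sensitivities(make_trials(2L, 1L, 1L), r), "3 trials")
})

test_that("sensitivities agree with the normal-equations oracle", {
  set.seed(55)
  for (i in 1:30) {
    n_items <- sample(6:10, 1)
    r <- make_ratings(taste = sample(1:5, n_items, TRUE),
                      health = sample(1:5, n_items, TRUE))
    targets <- sample(2:n_items, sample(4:8, 1), replace = TRUE)
    tr <- make_trials(targets, 1L, sample(-2:2, length(targets), TRUE))
    s <- estimate_sensitivities(tr, r)
    if (!s$ok) next
    X <- cbind(1, r$health[targets] - r$health[1],
               r$taste[targets] - r$taste[1])
    beta <- ols_oracle(X, tr$preference)
    expect_equal(s$health_sensitivity, beta[2], tolerance = 1e-10)
    expect_equal(s$taste_sensitivity, beta[3], tolerance = 1e-10)
  }
})

test_that("preference proportions count over all completed trials", {
  r <- make_ratings(taste = c(3, 4, 2, 5, 1, 3, 2, 4, 5, 1, 3),
                    health = c(3, 4, 5, 2, 1, 4, 3, 5, 1, 2, 3))
  # every preferred trial prefers the strictly healthier food
  tr <- make_trials(c(2L, 3L, 6L, 8L), 1L, c(1L, 2L, 1L, 2L))
  p <- preference_proportions(derive_trials(tr, r))
  expect_equal(p$prop_healthy, 1)

  # 10 completed, 4 with health_diff > 0, 2 neutral -> 0.4
  tr10 <- make_trials(c(2L, 3L, 6L, 8L, 4L, 5L, 9L, 3L, 7L, 11L), 1L,
                      c(1L, 1L, 1L, 1L, 1L, 1L, 1L, -2L, 0L, 0L))
  d10 <- derive_trials(tr10, r)
  expect_identical(sum(d10$health_diff > 0, na.rm = TRUE), 4L)
  p10 <- preference_proportions(d10)
  expect_equal(p10$prop_healthy, 0.4)
  expect_equal(p10$n_trials_completed, 10)
  expect_equal(p10$n_trials_preferred, 8)

  # all neutral: proportions are 0, not NaN
  pn <- preference_proportions(derive_trials(
    make_trials(c(2L, 3L), 1L, c(0L, 0L)), r))
  expect_equal(pn$prop_healthy, 0)
  expect_equal(pn$prop_tasty, 0)
})

test_that("RT trimming removes only trials beyond mean +/- 2.2 SD", {
  # constant RTs: zero SD, nothing removed
  tr <- make_trials(2:11, 1L, rep(1L, 10), rt = 800)
  out <- filter_rt_outliers(tr)
  expect_identical(nrow(out$removed), 0L)

  # 49 trials at 1000 ms and one at 10000: only the extreme one goes
  tr2 <- data.frame(participant_id = "P1", rt_ms = c(rep(1000, 49), 10000))
  out2 <- filter_rt_outliers(tr2)
  m <- mean(tr2$rt_ms); s <- sd(tr2$rt_ms)
  expect_true(10000 > m + 2.2 * s)
  expect_identical(nrow(out2$removed), 1L)
  expect_equal(out2$removed$rt_ms, 10000)
  expect_identical(out2$report$n_removed, 1L)

  # trimming is per participant by default: a slow participant is not
  # penalized for the fast participant's distribution
  set.seed(77)
  tr3 <- rbind(
    data.frame(participant_id = "fast", rt_ms = rnorm(50, 500, 10)),
    data.frame(participant_id = "slow", rt_ms = rnorm(50, 3000, 10))
  )
  out3 <- filter_rt_outliers(tr3)
  expect_lt(nrow(out3$removed), 10)
  pooled <- filter_rt_outliers(tr3, unit = "pooled")
  expect_identical(nrow(pooled$removed), 0L)  # bimodal pooled SD is huge
})
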