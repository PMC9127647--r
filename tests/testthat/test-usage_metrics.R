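# minimal finalized-session builder: one row per session, durations in
# minutes, start at noon UTC on activation-relative day offsets
mk_sessions <- function(user, day_offsets, dur_min, act_date,
                        read_share = 1) {
  start <- (as.numeric(act_date) + day_offsets) * 86400000 + 12 * 3600000
  tibble::tibble(
    user_id = user, session_index = seq_along(day_offsets),
    start_ms = start, last_click_ms = start + dur_min * 60000 / 2,
    end_ms = start + dur_min * 60000, click_count = 2L, terminal_end = FALSE,
    navigating_min = dur_min * (1 - read_share), reading_min = dur_min * read_share,
    account_min = 0, duration_min = dur_min)
}

test_that("lag, period and lapse partition the horizon", {
  act <- as.Date("2018-04-01")
  ss <- mk_sessions("U1", c(7, 50, 100), c(10, 5, 5), act)
  p <- compute_profile(ss, act)
  expect_equal(p$lag_days, 7)
  expect_equal(p$period_days, 93)
  expect_equal(p$lapse_days, 265)
  expect_equal(p$lag_days + p$period_days + p$lapse_days, 365)
  expect_true(p$dropout)  # lapse 265 >= 42
})

test_that("a single-day user is 100% active with rate equal to their minutes", {
  act <- as.Date("2018-04-01")
  p <- compute_profile(mk_sessions("U1", 3, 10, act), act)
  expect_equal(p$period_days, 0)
  expect_equal(p$active_days_pct, 100)
  expect_equal(p$rate_min_per_active_day, 10)
  expect_equal(p$n_sessions, 1L)
})

test_that("the ninety-day scripted user reproduces its hand-computed profile", {
  fx <- scripted_fixture("ninety_day_user")
  s <- build_sessions(fx$clicks)
  # all sessions terminal-ended: no imputation needed, but finalize via a
  # trivially fitted model for the full code path
  fit <- suppressWarnings(fit_duration_model(s$spans, lambda = -0.25))
  fin <- impute_final_durations(fit, s$sessions, s$spans)
  p <- compute_profiles(fin$sessions, fx$activations)
  expect_equal(p$n_sessions, fx$expected$n_sessions)
  expect_equal(p$lag_days, fx$expected$lag_days)
  expect_equal(p$period_days, fx$expected$period_days)
  expect_equal(p$lapse_days, fx$expected$lapse_days)
  expect_equal(p$total_minutes, fx$expected$total_minutes)
  expect_equal(p$active_days, fx$expected$active_days)
  expect_equal(p$active_days_pct, fx$expected$active_days_pct, tolerance = 1e-9)
  expect_equal(round(p$active_days_pct), 33)
  expect_equal(p$rate_min_per_active_day, fx$expected$rate_min_per_active_day)
})

test_that("activity percentages sum to 100 and never-users carry NA fields", {
  act <- as.Date("2018-04-01")
  ss <- dplyr::bind_rows(
    mk_sessions("U1", c(0, 10), c(4, 6), act, read_share = 0.7),
    mk_sessions("U2", 5, 8, act, read_share = 0.2))
  activ <- tibble::tibble(user_id = c("U1", "U2", "U3", "S1"),
                          activation_date = act)
  p <- compute_profiles(ss, activ, excluded_user_ids = "S1")
  expect_equal(sum(p$ever_user), 2L)
  ev <- p[p$ever_user, ]
  expect_equal(ev$pct_navigating + ev$pct_reading + ev$pct_account,
               c(100, 100), tolerance = 1e-6)
  nv <- p[!p$ever_user, ]
  expect_equal(nv$user_id, c("U3", "S1"))
  expect_true(all(is.na(nv$n_sessions)))
  expect_true(all(is.na(nv$rate_min_per_active_day)))
})

test_that("data-window violations are fatal", {
  act <- as.Date("2018-04-01")
  expect_error(compute_profile(mk_sessions("U1", -2, 5, act), act), "before activation")
  expect_error(compute_profile(mk_sessions("U1", 370, 5, act), act), "horizon")
})

test_that("adding a session never decreases count, minutes or active days", {
  act <- as.Date("2018-04-01")
  set.seed(77)
  days <- sort(sample(0:200, 10))
  durs <- runif(10, 1, 20)
  for (k in 5:9) {
    p1 <- compute_profile(mk_sessions("U1", days[1:k], durs[1:k], act), act)
    p2 <- compute_profile(mk_sessions("U1", days[1:(k + 1)], durs[1:(k + 1)], act), act)
    expect_gte(p2$n_sessions, p1$n_sessions)
    expect_gte(p2$total_minutes, p1$total_minutes)
    expect_gte(p2$active_days, p1$active_days)
  }
})

test_that("horizon identity and percentage closure hold across a synthetic cohort", {
  res <- test_pipeline_result()
  ev <- res$profiles[res$profiles$ever_user, ]
  expect_true(all(ev$lag_days + ev$period_days + ev$lapse_days == 365))
  expect_true(all(abs(ev$pct_navigating + ev$pct_reading + ev$pct_account - 100) < 1e-6))
  expect_true(all(ev$rate_min_per_active_day > 0))
  expect_true(all(ev$active_days_pct > 0 & ev$active_days_pct <= 100))
  expect_equal(ev$dropout, ev$lapse_days >= 42)
  # sessions and total time move together (cohort-level shape check)
  expect_gt(cor(ev$n_sessions, ev$total_minutes), 0.9)
})

test_that("the alternative active-day denominator is available", {
  act <- as.Date("2018-04-01")
  ss <- mk_sessions("U1", c(0, 30), c(5, 5), act)
  p1 <- compute_profiles(ss, tibble::tibble(user_id = "U1", activation_date = act))
  p2 <- compute_profiles(ss, tibble::tibble(user_id = "U1", activation_date = act),
                         active_day_denominator = "period")
  expect_equal(p1$active_days_pct, 100 * 2 / 31)
  expect_equal(p2$active_days_pct, 100 * 2 / 30)
})
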