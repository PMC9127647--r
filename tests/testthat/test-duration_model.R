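test_that("Box-Cox transform is exact at analytic points and round-trips", {
  expect_identical(boxcox_transform(1, -0.25), 0)
  expect_equal(boxcox_transform(16, -0.25), 2)  # 16^-0.25 = 0.5 exactly
  for (x in c(0.01, 1, 7.3, 120)) {
    expect_equal(inv_boxcox(boxcox_transform(x, -0.25), -0.25), x,
                 tolerance = 1e-12)
  }
  # lambda = 0 is the log limit
  expect_equal(boxcox_transform(exp(2), 0), 2)
  expect_equal(inv_boxcox(2, 0), exp(2))
  expect_error(boxcox_transform(-1, -0.25), "positive")
  expect_error(inv_boxcox(10, -0.25), "domain")
})

test_that("profile likelihood recovers the generating exponent", {
  set.seed(31)
  mu <- rnorm(10000, 0.2, 0.5)
  d <- inv_boxcox(mu, -0.25)
  est <- estimate_lambda(d)
  expect_lt(abs(est$lambda - (-0.25)), 0.05)
  # exactly log-normal durations: lambda near 0
  d0 <- exp(rnorm(10000, 0, 0.5))
  expect_lt(abs(estimate_lambda(d0)$lambda), 0.05)
})

test_that("profile likelihood agrees with the standard lm-based profile", {
  skip_if_not_installed("MASS")
  set.seed(32)
  sim <- simulate_spans(n_users = 50, spans_per_user = 30, seed = 5)
  df <- data.frame(d = sim$spans$duration_min, act = factor(sim$spans$activity))
  est <- estimate_lambda(df$d, df$act)
  bc <- MASS::boxcox(d ~ act, data = df, lambda = seq(-2, 2, 0.01),
                     plotit = FALSE)
  expect_equal(est$lambda, bc$x[which.max(bc$y)], tolerance = 0.011)
})

test_that("degenerate durations warn and fall back", {
  expect_warning(est <- estimate_lambda(rep(2, 200)), "degenerate")
  expect_equal(est$lambda, -0.25)
  expect_error(estimate_lambda(c(1, -1)), "non-positive")
  expect_warning(estimate_lambda(inv_boxcox(rnorm(50), -0.25)), "only 50")
})

test_that("mixed model recovers generating parameters on simulated spans", {
  p <- dwell_params()
  sim <- simulate_spans(n_users = 150, spans_per_user = 30, params = p, seed = 9)
  fit <- fit_duration_model(sim$spans, lambda = p$lambda)
  expect_equal(fit$beta_activity[[fit$reference]], 0)
  expect_lt(abs(fit$beta0 - p$beta0), 3 * fit$fixef_se[["(Intercept)"]])
  expect_lt(abs(fit$beta_activity[["READING"]] - p$beta_activity[["READING"]]),
            3 * fit$fixef_se[["activityREADING"]])
  expect_lt(abs(fit$sigma_u2 - p$sigma_u^2) / p$sigma_u^2, 0.25)
  expect_lt(abs(fit$sigma_e2 - p$sigma_e^2) / p$sigma_e^2, 0.1)
  # BLUPs track the true intercepts
  m <- merge(fit$user_blups, sim$truth$user_intercepts, by = "user_id")
  expect_gt(cor(m$blup, m$u), 0.8)
})

test_that("zero random-intercept variance yields a (near) singular fit", {
  p <- dwell_params(sigma_u = 0)
  sim <- simulate_spans(n_users = 80, spans_per_user = 20, params = p, seed = 10)
  fit <- suppressWarnings(fit_duration_model(sim$spans, lambda = p$lambda))
  expect_lt(fit$sigma_u2, 0.01)
})

test_that("degenerate designs still fit", {
  # single activity level: intercept + random effect
  sim <- simulate_spans(n_users = 30, spans_per_user = 10, seed = 11,
                        activity_probs = c(NAVIGATING = 1, READING = 0, ACCOUNT = 0))
  fit <- fit_duration_model(sim$spans, lambda = -0.25)
  expect_equal(unname(fit$beta_activity["NAVIGATING"]), 0)
  expect_true(is.finite(fit$beta0))
  # single user: plain linear model, sigma_u2 = 0
  one <- simulate_spans(n_users = 1, spans_per_user = 50, seed = 12)
  expect_warning(fit_duration_model(one$spans, lambda = -0.25), "single user")
  fit1 <- suppressWarnings(fit_duration_model(one$spans, lambda = -0.25))
  expect_equal(fit1$sigma_u2, 0)
})

test_that("imputation back-transforms the linear predictor and caps at the next session", {
  fit <- structure(list(lambda = -0.25, beta0 = boxcox_transform(2, -0.25),
                        beta_activity = c(NAVIGATING = 0, READING = 0, ACCOUNT = 0),
                        sigma_u2 = 0.05, sigma_e2 = 0.2,
                        user_blups = tibble::tibble(user_id = "U9", blup = 0.1),
                        reference = "NAVIGATING"),
                   class = "duration_model_fit")
  # a user with BLUP 0 and zero offsets: imputed duration is exactly 2 min
  expect_equal(predict_transformed(fit, "U1", "READING"),
               boxcox_transform(2, -0.25))
  cl <- clicks_from_gaps("U1", c(60000, 400000), rep("NAVIGATING", 3))
  s <- build_sessions(cl)
  fin <- impute_final_durations(fit, s$sessions, s$spans)
  cens <- !fin$spans$duration_known
  expect_equal(fin$spans$imputed_duration_min[cens][2], 2)  # last session uncapped
  expect_equal(fin$spans$imputed_duration_min[cens][1], 2)  # cap 400 s > 2 min
  # a 10-minute prediction against a next session starting 3 minutes after
  # the last click (2-minute timeout): capped to just under 3 minutes
  fit10 <- fit
  fit10$beta0 <- boxcox_transform(10, -0.25)
  cl2 <- clicks_from_gaps("U1", c(60000, 180000), rep("NAVIGATING", 3))
  s2 <- build_sessions(cl2, timeout_s = 120)
  fin2 <- impute_final_durations(fit10, s2$sessions, s2$spans)
  first_cens <- which(!fin2$spans$duration_known)[1]
  expect_lt(fin2$spans$imputed_duration_min[first_cens], 3)
  expect_equal(fin2$spans$imputed_duration_min[first_cens],
               (180000 - 1) / 60000)
  # known BLUP shifts the prediction
  expect_gt(predict_transformed(fit, "U9", "READING"),
            predict_transformed(fit, "U1", "READING"))
})

test_that("finalized sessions are disjoint with consistent activity minutes", {
  res <- test_pipeline_result()
  ss <- dplyr::arrange(res$sessions, user_id, session_index)
  same_user <- ss$user_id == dplyr::lag(ss$user_id, default = "")
  overlap <- same_user & (ss$start_ms <= dplyr::lag(ss$end_ms, default = -Inf))
  expect_false(any(overlap))
  expect_true(all(res$spans$imputed_duration_min[!res$spans$duration_known] > 0))
  # per-session activity minutes sum to the session duration (generator data
  # has no intra-session terminal clicks, so all time is attributed)
  tot <- ss$navigating_min + ss$reading_min + ss$account_min
  expect_equal(tot, ss$duration_min, tolerance = 1e-9)
})

test_that("with lambda -> 0 the fit agrees with a log-scale mixed model", {
  sim <- simulate_spans(n_users = 60, spans_per_user = 20,
                        params = dwell_params(lambda = 0), seed = 13)
  fit <- fit_duration_model(sim$spans, lambda = 0)
  df <- data.frame(y = log(sim$spans$duration_min),
                   activity = factor(sim$spans$activity,
                                     levels = c("NAVIGATING", "READING", "ACCOUNT")),
                   user_id = sim$spans$user_id)
  ref <- lme4::lmer(y ~ activity + (1 | user_id), data = df, REML = TRUE)
  expect_equal(fit$beta0, unname(lme4::fixef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$sigma_e2,
               as.data.frame(lme4::VarCorr(ref))$vcov[2], tolerance = 1e-6)
})
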