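#' Box-Cox power transformation
#'
#' `boxcox_transform(x, lambda)` computes `(x^lambda - 1) / lambda` for
#' positive `x` (the natural-log limit is used at `lambda = 0`);
#' `inv_boxcox()` is its inverse, `(1 + lambda * y)^(1/lambda)`, defined where
#' `1 + lambda * y > 0`.
#'
#' @param x Positive durations (minutes).
#' @param y Transformed values.
#' @param lambda Power parameter (dimensionless).
#' @return Numeric vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0, na.rm = TRUE)) abort("boxcox_transform requires strictly positive input")
  if (abs(lambda) < 1e-12) return(log(x))
  (x^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
inv_boxcox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) return(exp(y))
  base <- 1 + lambda * y
  if (any(base <= 0, na.rm = TRUE)) {
    abort(sprintf("inv_boxcox out of domain: 1 + lambda*y <= 0 (lambda = %g, min base = %g)",
                  lambda, min(base, na.rm = TRUE)))
  }
  base^(1 / lambda)
}

#' Estimate the Box-Cox exponent by profile likelihood
#'
#' Chooses `lambda` over a grid by maximising the profile log-likelihood of a
#' normal linear model for the transformed durations. When activity labels are
#' supplied the profiled model has an activity fixed effect (so the exponent
#' is not distorted by between-activity location shifts); otherwise an
#' intercept-only model is profiled. The estimate is deterministic given the
#' input.
#'
#' @param durations_min Known span durations, minutes, all positive.
#' @param activity Optional character vector of activity labels (same length).
#' @param grid Candidate lambda values (default `seq(-2, 2, by = 0.01)`).
#' @param fallback_lambda Returned (with a warning) when the durations are
#'   degenerate (zero variance). Default -0.25, the exponent typical of
#'   point-of-care reading dwell times.
#' @return List with `lambda`, `grid`, `loglik` (profile values), `n`.
#' @export
estimate_lambda <- function(durations_min, activity = NULL,
                            grid = seq(-2, 2, by = 0.01),
                            fallback_lambda = -0.25) {
  x <- durations_min
  if (any(x <= 0)) abort("non-positive duration passed to estimate_lambda")
  n <- length(x)
  if (n < 100) warn(sprintf("estimate_lambda: only %d known spans; estimate may be unstable", n))
  if (sd(x) < 1e-12) {
    warn("degenerate (constant) durations; returning fallback lambda")
    return(list(lambda = fallback_lambda, grid = grid,
                loglik = rep(NA_real_, length(grid)), n = n))
  }
  X <- if (is.null(activity) || length(unique(activity)) < 2) {
    matrix(1, n, 1)
  } else {
    model.matrix(~ factor(activity))
  }
  qx <- qr(X)
  sum_log_x <- sum(log(x))
  ll <- vapply(grid, function(l) {
    yt <- boxcox_transform(x, l)
    rss <- sum(qr.resid(qx, yt)^2)
    -n / 2 * log(rss / n) + (l - 1) * sum_log_x
  }, numeric(1))
  list(lambda = grid[which.max(ll)], grid = grid, loglik = ll, n = n)
}

#' Fit the dwell-time mixed model
#'
#' Fits, by REML, a linear mixed model for Box-Cox-transformed known span
#' durations with activity as a (up to) 3-level fixed effect and a per-user
#' random intercept:
#' `boxcox(duration) ~ activity + (1 | user)`.
#' Users' random intercepts are predicted by their BLUPs; users absent from
#' the training data are shrunk fully to the population mean (BLUP 0).
#'
#' @param spans Span tibble (from [build_sessions()]); only rows with
#'   `duration_known` are used.
#' @param lambda Box-Cox exponent. `NULL` (default) estimates it via
#'   [estimate_lambda()]; a number pins it.
#' @param reference Reference activity level (default `"NAVIGATING"`);
#'   predictions are invariant to this choice.
#' @return Object of class `duration_model_fit`: `lambda`, `beta0`,
#'   `beta_activity` (named, reference level exactly 0), `sigma_u2`,
#'   `sigma_e2`, `user_blups` (tibble), `fixef_se`, `n_spans`, `n_users`,
#'   `model` (the underlying `merMod`).
#' @export
fit_duration_model <- function(spans, lambda = NULL, reference = "NAVIGATING") {
  known <- spans[spans$duration_known, , drop = FALSE]
  if (nrow(known) < 2) abort("need at least 2 known spans to fit the duration model")
  single_user <- n_distinct(known$user_id) < 2
  if (single_user) {
    warn("duration model fitted on a single user; random-intercept variance is not identifiable and is set to 0")
  }
  if (is.null(lambda)) {
    lambda <- estimate_lambda(known$duration_min, known$activity)$lambda
  }
  if (abs(lambda) > 5) abort("implausible lambda (|lambda| > 5)")
  y <- boxcox_transform(known$duration_min, lambda)
  acts <- intersect(ACTIVITIES, unique(known$activity))
  if (!reference %in% acts) reference <- acts[1]
  lv <- c(reference, setdiff(acts, reference))
  df <- data.frame(y = y,
                   activity = factor(known$activity, levels = lv),
                   user_id = known$user_id)
  if (single_user) {
    fit <- stats::lm(if (length(lv) > 1) y ~ activity else y ~ 1, data = df)
    fe <- coef(fit)
    names(fe) <- sub("^\\(Intercept\\)$", "(Intercept)", names(fe))
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  } else {
    fml <- if (length(lv) > 1) y ~ activity + (1 | user_id) else y ~ 1 + (1 | user_id)
    fit <- lme4::lmer(fml, data = df, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  beta0 <- unname(fe[1])
  beta_activity <- setNames(rep(0, length(acts)), lv)
  if (length(lv) > 1) {
    for (a in lv[-1]) beta_activity[a] <- unname(fe[paste0("activity", a)])
  }
  if (single_user) {
    sigma_u2 <- 0
    sigma_e2 <- summary(fit)$sigma^2
    blups <- tibble(user_id = character(), blup = numeric())
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u2 <- vc$vcov[vc$grp == "user_id"]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
    if (sigma_u2 < 1e-10) {
      warn("singular fit: user random-intercept variance is (near) zero; BLUPs ~ 0")
    }
    re <- lme4::ranef(fit)$user_id
    blups <- tibble(user_id = rownames(re), blup = re[["(Intercept)"]])
  }
  structure(list(lambda = lambda,
                 beta0 = beta0,
                 beta_activity = beta_activity,
                 sigma_u2 = sigma_u2,
                 sigma_e2 = sigma_e2,
                 user_blups = blups,
                 fixef_se = setNames(se, names(fe)),
                 reference = lv[1],
                 n_spans = nrow(known),
                 n_users = n_distinct(known$user_id),
                 model = fit),
            class = "duration_model_fit")
}

#' @export
print.duration_model_fit <- function(x, ...) {
  cat("Box-Cox dwell-time mixed model\n")
  cat(sprintf("  lambda      : %.3f\n", x$lambda))
  cat(sprintf("  intercept   : %.3f (transformed scale, ref = %s)\n", x$beta0, x$reference))
  for (a in names(x$beta_activity)) {
    if (a != x$reference) cat(sprintf("  %-12s: %+.3f\n", a, x$beta_activity[[a]]))
  }
  cat(sprintf("  sigma_u^2   : %.4f   sigma_e^2 : %.4f\n", x$sigma_u2, x$sigma_e2))
  cat(sprintf("  fitted on %d spans from %d users\n", x$n_spans, x$n_users))
  invisible(x)
}

#' Predicted transformed dwell for user/activity pairs
#'
#' Linear predictor `beta0 + beta_activity + BLUP(user)` on the transformed
#' scale; unseen users get BLUP 0.
#'
#' @param fit A `duration_model_fit`.
#' @param user_id,activity Character vectors (recycled to common length).
#' @return Numeric vector of transformed-scale predictions.
#' @export
predict_transformed <- function(fit, user_id, activity) {
  stopifnot(inherits(fit, "duration_model_fit"))
  blup <- fit$user_blups$blup[match(user_id, fit$user_blups$user_id)]
  blup[is.na(blup)] <- 0
  offs <- fit$beta_activity[activity]
  offs[is.na(offs)] <- 0  # activity absent from training: population intercept
  unname(fit$beta0 + offs + blup)
}

#' Impute censored final-span durations and finalize sessions
#'
#' For each censored span the model's point prediction on the transformed
#' scale is back-transformed to minutes (no smearing correction — a known
#' downward-bias choice on the natural scale). The imputed duration is capped
#' so a session never reaches the user's next session start (cap: next start
#' minus last click minus 1 ms); the user's last session is uncapped. Session
#' end times, total durations, and per-activity minutes are then finalized.
#'
#' @param fit A [fit_duration_model()] result.
#' @param sessions,spans As returned by [build_sessions()].
#' @return List with finalized `sessions` (columns `end_ms`, `duration_min`
#'   and per-activity minutes `navigating_min`, `reading_min`, `account_min`
#'   filled) and `spans` (`imputed_duration_min` filled for censored rows).
#' @export
impute_final_durations <- function(fit, sessions, spans) {
  stopifnot(inherits(fit, "duration_model_fit"))
  cen <- !spans$duration_known
  if (any(cen)) {
    pred <- predict_transformed(fit, spans$user_id[cen], spans$activity[cen])
    imput <- inv_boxcox(pred, fit$lambda)
    # cap against the next session of the same user
    ord <- order(sessions$user_id, sessions$session_index)
    ss <- sessions[ord, , drop = FALSE]
    next_start <- ifelse(ss$user_id == dplyr::lead(ss$user_id, default = ""),
                         dplyr::lead(ss$start_ms), NA_real_)
    key <- paste(ss$user_id, ss$session_index)
    cap_ms <- (next_start - ss$last_click_ms - 1)
    cap_min <- cap_ms[match(paste(spans$user_id[cen], spans$session_index[cen]), key)] / MS_PER_MIN
    imput <- ifelse(!is.na(cap_min), pmin(imput, cap_min), imput)
    if (any(imput <= 0)) abort("non-positive imputed duration (capping produced an overlap?)")
    spans$imputed_duration_min[cen] <- imput
    spans$end_ms[cen] <- spans$start_ms[cen] + imput * MS_PER_MIN
  }
  eff_min <- ifelse(spans$duration_known, spans$duration_min, spans$imputed_duration_min)

  per_act <- spans |>
    mutate(eff_min = eff_min) |>
    group_by(.data$user_id, .data$session_index) |>
    summarise(navigating_min = sum(.data$eff_min[.data$activity == "NAVIGATING"]),
              reading_min = sum(.data$eff_min[.data$activity == "READING"]),
              account_min = sum(.data$eff_min[.data$activity == "ACCOUNT"]),
              span_end_ms = max(.data$end_ms),
              .groups = "drop")

  sessions <- sessions |>
    left_join(per_act, by = c("user_id", "session_index")) |>
    mutate(navigating_min = ifelse(is.na(.data$navigating_min), 0, .data$navigating_min),
           reading_min = ifelse(is.na(.data$reading_min), 0, .data$reading_min),
           account_min = ifelse(is.na(.data$account_min), 0, .data$account_min),
           end_ms = ifelse(.data$terminal_end, .data$last_click_ms,
                           pmax(.data$span_end_ms, .data$last_click_ms, na.rm = TRUE)),
           duration_min = (.data$end_ms - .data$start_ms) / MS_PER_MIN) |>
    select(-"span_end_ms")

  list(sessions = sessions, spans = spans)
}
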