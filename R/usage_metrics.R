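#' Per-user usage statistics
#'
#' Computes, for every enrolled user, the eight usage statistics that drive
#' segmentation, from finalized sessions (ends imputed) and the activation
#' record:
#'
#' * `n_sessions` — number of sessions over the horizon;
#' * `total_minutes` — summed session durations;
#' * `pct_navigating` / `pct_reading` / `pct_account` — percentage of
#'   attributed online time per activity (sums to 100);
#' * `lag_days` — days from activation email to first click;
#' * `period_days` — days from first to last click;
#' * `active_days_pct` — percentage of days in the period of use with at
#'   least one session start (denominator `period_days + 1` by default, so a
#'   single-day user is 100% active);
#' * `rate_min_per_active_day` — average minutes online per active day;
#' * `lapse_days` — days from last click to the end of the horizon.
#'
#' All day arithmetic is in calendar days (UTC), so
#' `lag + period + lapse = horizon_days` holds exactly for every ever-user.
#' A user is a *dropout* when their lapse is at least `dropout_lapse_days`
#' (default 42 = 6 weeks). Users with no retained clicks (including users
#' excluded for having exactly one click) receive `ever_user = FALSE` and NA
#' usage fields.
#'
#' @param sessions Finalized session tibble (see [impute_final_durations()]).
#' @param activations Tibble `user_id`, `activation_date` (Date) covering
#'   every user in `sessions`.
#' @param excluded_user_ids Users removed upstream (single-click rule); they
#'   are reported as never-users.
#' @param horizon_days Observation window length in days after activation
#'   (default 365).
#' @param dropout_lapse_days Minimum lapse, in days, defining a dropout
#'   (default 42).
#' @param active_day_denominator `"period_plus_1"` (default, inclusive of
#'   both endpoints) or `"period"`.
#' @return Tibble with one row per user in `activations`.
#' @export
compute_profiles <- function(sessions, activations,
                             excluded_user_ids = character(),
                             horizon_days = 365,
                             dropout_lapse_days = 42,
                             active_day_denominator = c("period_plus_1", "period")) {
  active_day_denominator <- match.arg(active_day_denominator)
  stopifnot(all(c("user_id", "activation_date") %in% names(activations)))
  missing_act <- setdiff(unique(sessions$user_id), activations$user_id)
  if (length(missing_act) > 0) {
    abort(sprintf("clickstream user(s) missing from activation table: %s",
                  paste(head(missing_act, 5), collapse = ", ")))
  }
  if (nrow(sessions) > 0 && any(is.na(sessions$end_ms))) {
    abort("sessions must be finalized (imputed end times) before computing profiles")
  }

  if (nrow(sessions) == 0) {
    stats <- tibble(user_id = character(), n_sessions = integer(),
                    total_minutes = numeric(), navigating_min = numeric(),
                    reading_min = numeric(), account_min = numeric(),
                    first_day = numeric(), last_click_day = numeric(),
                    active_days = integer())
  } else {
    stats <- sessions |>
      mutate(start_day = floor(.data$start_ms / MS_PER_DAY),
             last_day = floor(.data$last_click_ms / MS_PER_DAY)) |>
      group_by(.data$user_id) |>
      summarise(n_sessions = n(),
                total_minutes = sum(.data$duration_min),
                navigating_min = sum(.data$navigating_min),
                reading_min = sum(.data$reading_min),
                account_min = sum(.data$account_min),
                first_day = min(.data$start_day),
                last_click_day = max(.data$last_day),
                active_days = n_distinct(.data$start_day),
                .groups = "drop")
  }

  prof <- activations |>
    left_join(stats, by = "user_id") |>
    mutate(ever_user = !is.na(.data$n_sessions) &
             !(.data$user_id %in% excluded_user_ids))
  if (any(prof$ever_user & (prof$user_id %in% excluded_user_ids))) {
    abort("excluded users still present in sessions")  # defensive; unreachable
  }

  aday <- as.numeric(prof$activation_date)
  prof <- prof |>
    mutate(lag_days = ifelse(.data$ever_user, .data$first_day - aday, NA_real_),
           period_days = ifelse(.data$ever_user, .data$last_click_day - .data$first_day, NA_real_),
           lapse_days = ifelse(.data$ever_user,
                               horizon_days - .data$lag_days - .data$period_days, NA_real_))

  ev <- prof$ever_user & !is.na(prof$lag_days)
  if (any(prof$lag_days[ev] < 0)) abort("click before activation date (data window violation)")
  if (any(prof$lag_days[ev] + prof$period_days[ev] > horizon_days)) {
    abort("click beyond activation + horizon (data window violation)")
  }

  attributed <- prof$navigating_min + prof$reading_min + prof$account_min
  denom <- if (active_day_denominator == "period_plus_1") {
    prof$period_days + 1
  } else {
    pmax(prof$period_days, 1)
  }
  prof |>
    mutate(pct_navigating = ifelse(.data$ever_user & attributed > 0,
                                   100 * .data$navigating_min / attributed, NA_real_),
           pct_reading = ifelse(.data$ever_user & attributed > 0,
                                100 * .data$reading_min / attributed, NA_real_),
           pct_account = ifelse(.data$ever_user & attributed > 0,
                                100 * .data$account_min / attributed, NA_real_),
           active_days_pct = ifelse(.data$ever_user, 100 * .data$active_days / denom, NA_real_),
           rate_min_per_active_day = ifelse(.data$ever_user,
                                            .data$total_minutes / .data$active_days, NA_real_),
           dropout = ifelse(.data$ever_user, .data$lapse_days >= dropout_lapse_days, NA),
           n_sessions = ifelse(.data$ever_user, .data$n_sessions, NA_integer_),
           total_minutes = ifelse(.data$ever_user, .data$total_minutes, NA_real_)) |>
    select("user_id", "activation_date", "ever_user", "n_sessions", "total_minutes",
           "pct_navigating", "pct_reading", "pct_account",
           "lag_days", "period_days", "lapse_days",
           "active_days", "active_days_pct", "rate_min_per_active_day", "dropout")
}

#' Usage profile for a single user
#'
#' Convenience wrapper over [compute_profiles()] for one user's sessions.
#'
#' @param sessions Finalized sessions of one user.
#' @param activation_date The user's activation date (Date).
#' @inheritParams compute_profiles
#' @return One-row profile tibble.
#' @export
compute_profile <- function(sessions, activation_date, horizon_days = 365,
                            dropout_lapse_days = 42) {
  stopifnot(n_distinct(sessions$user_id) <= 1)
  uid <- if (nrow(sessions) > 0) sessions$user_id[1] else "user"
  compute_profiles(sessions,
                   tibble(user_id = uid, activation_date = as.Date(activation_date)),
                   horizon_days = horizon_days,
                   dropout_lapse_days = dropout_lapse_days)
}
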