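#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline in one flat object:
#' the 500 ms double-click threshold, the 5-minute session timeout, the
#' Box-Cox exponent mode (`"auto"` re-estimates it by profile likelihood; a
#' number such as -0.25 pins it), the 365-day observation horizon, the
#' 5 min/active-day and 48-week segment cut points, and the 42-day dropout
#' lapse.
#'
#' @param double_click_threshold_ms Minimum same-user inter-click gap (ms).
#' @param session_timeout_s Inactivity timeout delimiting sessions (s).
#' @param lambda `"auto"` or a fixed Box-Cox exponent.
#' @param horizon_days Observation window after activation (days).
#' @param heavy_rate_min Heavy-use cut point (min per active day).
#' @param longterm_weeks Long-term cut point (weeks of period of use).
#' @param dropout_lapse_days Minimum lapse defining a dropout (days).
#' @param covariates Covariates to tabulate in the report stage.
#' @param adjusters Adjuster set for adjusted distributions (NULL = raw
#'   tables only).
#' @param active_day_denominator See [compute_profiles()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(double_click_threshold_ms = 500,
                            session_timeout_s = 300,
                            lambda = "auto",
                            horizon_days = 365,
                            heavy_rate_min = 5,
                            longterm_weeks = 48,
                            dropout_lapse_days = 42,
                            covariates = character(),
                            adjusters = NULL,
                            active_day_denominator = "period_plus_1") {
  stopifnot(double_click_threshold_ms > 0, session_timeout_s > 0,
            horizon_days > 0, heavy_rate_min > 0, longterm_weeks > 0,
            dropout_lapse_days > 0)
  if (!(identical(lambda, "auto") || is.numeric(lambda))) {
    abort("lambda must be \"auto\" or a number")
  }
  structure(list(double_click_threshold_ms = double_click_threshold_ms,
                 session_timeout_s = session_timeout_s,
                 lambda = lambda,
                 horizon_days = horizon_days,
                 heavy_rate_min = heavy_rate_min,
                 longterm_weeks = longterm_weeks,
                 dropout_lapse_days = dropout_lapse_days,
                 covariates = covariates,
                 adjusters = adjusters,
                 active_day_denominator = active_day_denominator),
            class = "pipeline_config")
}

#' Run the full clickstream-to-segments pipeline
#'
#' Chains every stage: click filtering (double-click removal, single-click
#' exclusion), activity classification, sessionization, Box-Cox mixed-model
#' fitting and censored-duration imputation, per-user usage statistics,
#' segment assignment, and (when survey data and covariates are supplied)
#' segment-by-covariate reporting. Inputs may be tibbles or file paths.
#' The returned manifest records stage-by-stage counts satisfying click
#' conservation: clicks in = retained + double-click-removed +
#' single-click-removed + parse-rejected.
#'
#' @param clickstream Click tibble (`user_id`, `timestamp_ms`, `event_type`)
#'   or a CSV path for [read_clickstream()].
#' @param activations Activation tibble or CSV path.
#' @param survey Optional survey tibble or CSV path.
#' @param map An [activity_map()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs
#'   (sessions, spans, profiles, segments, report tables) and
#'   `manifest.json` are written there.
#' @return List of class `pipeline_result`: `sessions`, `spans`, `profiles`,
#'   `segments`, `fit` (the duration model), `manifest`.
#' @export
run_pipeline <- function(clickstream, activations, survey = NULL,
                         map = activity_map(), config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_rejected <- 0L
  if (is.character(clickstream)) {
    rd <- read_clickstream(clickstream)
    clicks <- rd$clicks
    n_rejected <- rd$n_rejected
  } else {
    clicks <- sort_clicks(as_tibble(clickstream))
  }
  if (is.character(activations)) activations <- read_activations(activations)
  if (is.character(survey)) survey <- read_survey(survey)
  n_in <- nrow(clicks) + n_rejected

  dc <- remove_double_clicks(clicks, config$double_click_threshold_ms)
  sc <- drop_single_click_users(dc$clicks)
  classified <- classify_clicks(sc$clicks, map)
  sess <- sessionize_all(classified, config$session_timeout_s)

  lambda <- if (identical(config$lambda, "auto")) NULL else config$lambda
  fit <- fit_duration_model(sess$spans, lambda = lambda)
  fin <- impute_final_durations(fit, sess$sessions, sess$spans)

  profiles <- compute_profiles(fin$sessions, activations,
                               excluded_user_ids = sc$excluded_user_ids,
                               horizon_days = config$horizon_days,
                               dropout_lapse_days = config$dropout_lapse_days,
                               active_day_denominator = config$active_day_denominator)
  segments <- assign_segments(profiles,
                              segment_thresholds(config$heavy_rate_min,
                                                 config$longterm_weeks))
  cohort_tab <- segment_cohort(segments)

  manifest <- list(
    n_clicks_in = n_in,
    n_rejected_rows = n_rejected,
    n_double_clicks_removed = dc$n_removed,
    n_single_click_users = length(sc$excluded_user_ids),
    n_single_click_clicks_removed = length(sc$excluded_user_ids),
    n_clicks_retained = nrow(classified),
    n_clicks_dropped_unmapped = nrow(sc$clicks) - nrow(classified),
    n_sessions = sess$summary$n_sessions,
    n_discarded_terminal_sessions = sess$summary$n_discarded_terminal_sessions,
    n_users_cohort = nrow(activations),
    n_ever_users = sum(segments$ever_user),
    n_never_users = sum(!segments$ever_user),
    lambda = fit$lambda,
    segment_counts = setNames(as.list(cohort_tab$n), cohort_tab$segment),
    config = unclass(config),
    input_hash = list(clicks = rlang::hash(clicks),
                      activations = rlang::hash(activations))
  )

  result <- structure(list(sessions = fin$sessions, spans = fin$spans,
                           profiles = profiles, segments = segments,
                           cohort_table = cohort_tab, fit = fit,
                           manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(fin$sessions, file.path(out_dir, "sessions.csv"))
    readr::write_csv(fin$spans, file.path(out_dir, "spans.csv"))
    readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
    readr::write_csv(select(segments, "user_id", "segment", "is_longterm",
                            "is_heavy", "period_days", "rate_min_per_active_day"),
                     file.path(out_dir, "segments.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(survey) && length(config$covariates) > 0) {
      report_segments(segments, survey, config$covariates,
                      adjusters = config$adjusters,
                      out_dir = file.path(out_dir, "report"))
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("clickstream segmentation pipeline\n")
  cat(sprintf("  clicks in %d | retained %d | double-clicks removed %d | single-click users %d\n",
              m$n_clicks_in, m$n_clicks_retained, m$n_double_clicks_removed,
              m$n_single_click_users))
  cat(sprintf("  sessions %d | users %d (ever %d / never %d) | lambda %.2f\n",
              m$n_sessions, m$n_users_cohort, m$n_ever_users, m$n_never_users,
              m$lambda))
  cat("  segments: ",
      paste(sprintf("%s=%d", names(m$segment_counts), unlist(m$segment_counts)),
            collapse = " "), "\n")
  invisible(x)
}
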