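#' Group clicks into sessions and activity spans
#'
#' Splits each user's filtered, activity-classified clicks into sessions using
#' an inactivity timeout: a click starting `timeout_s` seconds or more after
#' the previous click of the same user opens a new session (a gap strictly
#' less than the timeout keeps the same session). Within a session, every
#' non-terminal click opens an activity span that ends at the next click's
#' timestamp; the final non-terminal click of a session opens a *censored*
#' span whose duration is unknown until imputation. Terminal clicks close the
#' preceding span at their timestamp and never open one; a session consisting
#' only of terminal clicks is discarded as a zero-duration artifact (counted
#' in the summary).
#'
#' @param clicks Tibble with `user_id`, `timestamp_ms`, `event_type`,
#'   `activity` (see [classify_clicks()]), filtered by
#'   [remove_double_clicks()].
#' @param timeout_s Inactivity timeout in seconds (default 300 = 5 minutes).
#' @return A list with:
#'   * `sessions`: tibble `user_id`, `session_index`, `start_ms`,
#'     `last_click_ms`, `end_ms` (known only for terminal-ended sessions until
#'     imputation), `click_count`, `terminal_end`;
#'   * `spans`: tibble `user_id`, `session_index`, `span_index`, `activity`,
#'     `start_ms`, `end_ms` (NA when censored), `duration_known`,
#'     `duration_min` (NA when censored), `imputed_duration_min` (NA until
#'     imputation);
#'   * `summary`: list with `n_clicks`, `n_sessions`,
#'     `n_discarded_terminal_sessions`.
#' @export
build_sessions <- function(clicks, timeout_s = 300) {
  stopifnot(timeout_s > 0)
  if (nrow(clicks) == 0) {
    return(list(sessions = empty_sessions(), spans = empty_spans(),
                summary = list(n_clicks = 0L, n_sessions = 0L,
                               n_discarded_terminal_sessions = 0L)))
  }
  if (!"activity" %in% names(clicks)) {
    abort("clicks must carry an activity column; run classify_clicks() first")
  }
  if (any(is.na(clicks$activity)) || !all(clicks$activity %in% ACTIVITY_CLASSES)) {
    abort("unclassified activity reached the sessionizer (upstream contract violation)")
  }
  timeout_ms <- timeout_s * 1000
  cl <- sort_clicks(clicks)
  gap <- cl$timestamp_ms - dplyr::lag(cl$timestamp_ms)
  new_user <- cl$user_id != dplyr::lag(cl$user_id, default = "")
  new_session <- new_user | is.na(gap) | gap >= timeout_ms
  # global session id, then per-user index
  sid <- cumsum(new_session)
  cl$.sid <- sid

  sessions <- cl |>
    group_by(.data$user_id, .data$.sid) |>
    summarise(start_ms = first(.data$timestamp_ms),
              last_click_ms = last(.data$timestamp_ms),
              click_count = n(),
              terminal_end = last(.data$activity) == "TERMINAL",
              all_terminal = all(.data$activity == "TERMINAL"),
              .groups = "drop") |>
    arrange(.data$user_id, .data$start_ms)

  n_discard <- sum(sessions$all_terminal)
  discarded_sids <- sessions$.sid[sessions$all_terminal]
  sessions <- sessions[!sessions$all_terminal, , drop = FALSE]
  sessions <- sessions |>
    group_by(.data$user_id) |>
    mutate(session_index = row_number()) |>
    ungroup()
  sessions$end_ms <- ifelse(sessions$terminal_end, sessions$last_click_ms, NA_real_)

  cl <- cl[!(cl$.sid %in% discarded_sids), , drop = FALSE]
  cl$session_index <- sessions$session_index[match(cl$.sid, sessions$.sid)]

  # spans: every non-terminal click opens one; end at next click in session
  spans <- cl |>
    group_by(.data$.sid) |>
    mutate(next_ts = lead(.data$timestamp_ms)) |>
    ungroup() |>
    filter(.data$activity != "TERMINAL") |>
    mutate(start_ms = .data$timestamp_ms,
           end_ms = .data$next_ts,
           duration_known = !is.na(.data$next_ts),
           duration_min = (.data$end_ms - .data$start_ms) / MS_PER_MIN,
           imputed_duration_min = NA_real_) |>
    group_by(.data$.sid) |>
    mutate(span_index = row_number()) |>
    ungroup() |>
    select("user_id", "session_index", "span_index", "activity",
           "start_ms", "end_ms", "duration_known", "duration_min",
           "imputed_duration_min")

  if (any(spans$duration_known & spans$duration_min <= 0)) {
    abort("non-positive known span duration; was double-click filtering applied?")
  }

  sessions <- select(sessions, "user_id", "session_index", "start_ms",
                     "last_click_ms", "end_ms", "click_count", "terminal_end")
  list(sessions = sessions, spans = spans,
       summary = list(n_clicks = nrow(cl),
                      n_sessions = nrow(sessions),
                      n_discarded_terminal_sessions = n_discard))
}

#' Sessionize a full cohort and report run counts
#'
#' Thin wrapper over [build_sessions()] that also reports per-user session
#' counts, for run manifests.
#'
#' @inheritParams build_sessions
#' @return As [build_sessions()], plus `per_user` (tibble `user_id`,
#'   `n_sessions`).
#' @export
sessionize_all <- function(clicks, timeout_s = 300) {
  res <- build_sessions(clicks, timeout_s)
  res$per_user <- res$sessions |> count(.data$user_id, name = "n_sessions")
  res
}

empty_sessions <- function() {
  tibble(user_id = character(), session_index = integer(), start_ms = numeric(),
         last_click_ms = numeric(), end_ms = numeric(), click_count = integer(),
         terminal_end = logical())
}

empty_spans <- function() {
  tibble(user_id = character(), session_index = integer(), span_index = integer(),
         activity = character(), start_ms = numeric(), end_ms = numeric(),
         duration_known = logical(), duration_min = numeric(),
         imputed_duration_min = numeric())
}
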