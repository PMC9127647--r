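#' Hand-written miniature fixtures with known expectations
#'
#' Returns tiny, fully hand-computed clickstreams for exercising individual
#' pipeline stages:
#'
#' * `"fig2_session"` — one user, clicks at minutes 0, 2, 4 and 30: two
#'   sessions under the 5-minute timeout, with two known 2-minute spans and a
#'   censored span per session;
#' * `"boundary_300s"` — two users with gaps of exactly 300 s (splits into
#'   two sessions) and 299.999 s (stays one session);
#' * `"terminal_final"` — a session closed by an external-link click, so no
#'   span is censored and the session end is observed;
#' * `"ninety_day_user"` — 30 active days spread over a 90-day period of use
#'   (lag 7), one terminal-ended 4.5-minute session per active day: 135 total
#'   minutes, rate 4.5 min per active day, active-day percentage 100*30/91.
#'
#' @param name Fixture id (see above).
#' @return List with `clicks` (classified click tibble), `activations`, and
#'   `expected` (named list of hand-computed values).
#' @export
scripted_fixture <- function(name = c("fig2_session", "boundary_300s",
                                      "terminal_final", "ninety_day_user")) {
  name <- match.arg(name)
  act_date <- as.Date("2018-03-05")
  day0 <- as.numeric(act_date) * MS_PER_DAY
  mk <- function(user, min_offsets, events, day_offset = 0) {
    tibble(user_id = user,
           timestamp_ms = day0 + day_offset * MS_PER_DAY +
             12 * 3600000 + min_offsets * MS_PER_MIN,
           event_type = events)
  }
  switch(name,
    fig2_session = {
      clicks <- mk("U1", c(0, 2, 4, 30),
                   c("Search", "TopicView", "TopicSectionView", "Search"),
                   day_offset = 7)
      list(clicks = classify_clicks(clicks),
           activations = tibble(user_id = "U1", activation_date = act_date),
           expected = list(n_sessions = 2L,
                           session_sizes = c(3L, 1L),
                           known_span_min = c(2, 2),
                           n_censored = 2L))
    },
    boundary_300s = {
      clicks <- bind_rows(
        mk("U1", c(0, 5), c("Search", "TopicView")),          # gap == 300 s
        mk("U2", c(0, 5 - 0.001 / 60), c("Search", "TopicView")))  # 299.999 s
      list(clicks = classify_clicks(clicks),
           activations = tibble(user_id = c("U1", "U2"),
                                activation_date = act_date),
           expected = list(n_sessions_by_user = c(U1 = 2L, U2 = 1L)))
    },
    terminal_final = {
      clicks <- mk("U1", c(0, 0.5, 1.5),
                   c("Search", "TopicView", "ExternalLinkClick"))
      list(clicks = classify_clicks(clicks),
           activations = tibble(user_id = "U1", activation_date = act_date),
           expected = list(n_sessions = 1L,
                           span_min = c(NAVIGATING = 0.5, READING = 1),
                           session_duration_min = 1.5,
                           n_censored = 0L))
    },
    ninety_day_user = {
      offsets <- 7 + round(seq(0, 90, length.out = 30))
      clicks <- bind_rows(lapply(offsets, function(d) {
        mk("U1", c(0, 1.5, 4.5),
           c("Search", "TopicView", "ExternalLinkClick"), day_offset = d)
      }))
      list(clicks = classify_clicks(clicks),
           activations = tibble(user_id = "U1", activation_date = act_date),
           expected = list(n_sessions = 30L,
                           lag_days = 7, period_days = 90, lapse_days = 268,
                           total_minutes = 135,
                           active_days = 30L,
                           active_days_pct = 100 * 30 / 91,
                           rate_min_per_active_day = 4.5))
    })
}
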