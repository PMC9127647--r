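#' Dwell-time model parameters
#'
#' Parameters of the Box-Cox-normal dwell model used by the generator:
#' on the transformed scale a span's duration is
#' `Normal(beta0 + beta_activity + u_user, sigma_e)` with
#' `u_user ~ Normal(0, sigma_u)`, back-transformed with exponent `lambda`.
#' Defaults give median dwells of about 0.5 min (navigating), 1.2 min
#' (reading) and 0.45 min (account management), in line with brief
#' point-of-care lookups.
#'
#' @param lambda Box-Cox exponent (default -0.25).
#' @param beta0 Transformed-scale intercept (reference activity NAVIGATING).
#' @param beta_activity Named offsets for READING and ACCOUNT.
#' @param sigma_u User random-intercept SD.
#' @param sigma_e Residual SD.
#' @param family `"boxcox"` (the model above) or `"lognormal_heavy"`
#'   (misspecification switch: log-normal dwells with inflated spread, for
#'   robustness checks).
#' @return A named list of class `dwell_params`.
#' @export
dwell_params <- function(lambda = -0.25, beta0 = -0.75,
                         beta_activity = c(READING = 0.95, ACCOUNT = -0.1),
                         sigma_u = 0.25, sigma_e = 0.4,
                         family = c("boxcox", "lognormal_heavy")) {
  family <- match.arg(family)
  stopifnot(sigma_u >= 0, sigma_e > 0, abs(lambda) <= 5,
            all(c("READING", "ACCOUNT") %in% names(beta_activity)))
  structure(list(lambda = lambda, beta0 = beta0, beta_activity = beta_activity,
                 sigma_u = sigma_u, sigma_e = sigma_e, family = family),
            class = "dwell_params")
}

#' Synthetic cohort generator configuration
#'
#' Configuration for [generate_cohort()]. Defaults describe a cohort of
#' clinicians receiving a one-year subscription: a 9-week enrollment window,
#' a five-way latent segment mix (25/15/24/22/15% for A/B/C/D/E), per-segment
#' activity patterns separated well away from the 5-minute and 48-week cut
#' points, Box-Cox-normal dwell times, a small double-click artifact rate and
#' a small share of single-click users.
#'
#' Per-segment behavior: lag is geometric (most users start within days);
#' short-term segments (A, B) draw a period of use of 14-280 days, long-term
#' segments (C, D) 343 days up to the horizon; each day in the period is
#' active with a segment-specific probability (first and last day always
#' active); sessions per active day and clicks per session are shifted
#' Poisson, heavier for B and C so their rate of use clears 5 minutes per
#' active day while A and D stay below it.
#'
#' @param n_users Cohort size.
#' @param seed Integer seed; all randomness flows from it.
#' @param segment_mix Named probabilities for segments A-E (sums to 1).
#' @param dwell A [dwell_params()] object.
#' @param segment_behavior Named list (A-D) of lists with `p_active`,
#'   `extra_sessions` (Poisson mean above 1 per active day), `extra_clicks`
#'   (Poisson mean above 2 per session).
#' @param lag_geom_prob Geometric success probability for the lag in days.
#' @param double_click_rate Probability a click spawns a duplicate within
#'   500 ms.
#' @param single_click_user_rate Probability an active user is truncated to a
#'   single click (excluded downstream, treated as a never-user).
#' @param terminal_final_rate Probability a session ends with a terminal
#'   (external-link) click, making its final span duration observed.
#' @param activity_transitions 3x3 row-stochastic matrix of activity-to-
#'   activity transitions (rows/cols NAVIGATING, READING, ACCOUNT).
#' @param event_probs Named list: per activity, a named probability vector
#'   over event types (must be mapped by [default_activity_map()] or your
#'   map).
#' @param covariate_effects Named list: per covariate, `levels`, `base`
#'   (baseline level probabilities) and optional `shift`, a levels-by-segment
#'   log-odds matrix tilting level probabilities within each segment (this
#'   induces the covariate-segment association while leaving the marginal
#'   segment mix exact).
#' @param start_date First activation date of the enrollment window.
#' @param enroll_days Length of the enrollment window in days.
#' @param horizon_days Observation window after activation.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_users = 1000,
                             seed = 1L,
                             segment_mix = c(A = 0.25, B = 0.15, C = 0.24,
                                             D = 0.21, E = 0.15),
                             dwell = dwell_params(),
                             segment_behavior = default_segment_behavior(),
                             lag_geom_prob = 0.15,
                             double_click_rate = 0.03,
                             single_click_user_rate = 0.01,
                             terminal_final_rate = 0.10,
                             activity_transitions = default_activity_transitions(),
                             event_probs = default_event_probs(),
                             covariate_effects = default_covariate_effects(),
                             start_date = as.Date("2018-03-01"),
                             enroll_days = 63,
                             horizon_days = 365) {
  stopifnot(n_users >= 1, length(segment_mix) == 5,
            all(names(segment_mix) == c("A", "B", "C", "D", "E")))
  if (abs(sum(segment_mix) - 1) > 1e-9) abort("segment_mix must sum to 1")
  stopifnot(inherits(dwell, "dwell_params"))
  stopifnot(all(c("A", "B", "C", "D") %in% names(segment_behavior)))
  if (!all(abs(rowSums(activity_transitions) - 1) < 1e-9)) {
    abort("activity_transitions rows must sum to 1")
  }
  stopifnot(double_click_rate >= 0, double_click_rate < 1,
            single_click_user_rate >= 0, single_click_user_rate < 1,
            terminal_final_rate >= 0, terminal_final_rate < 1)
  # dwell feasibility: within-session gaps must fit under the 300 s timeout
  cap_t <- boxcox_transform(GEN_DWELL_CAP_MIN, dwell$lambda)
  mus <- dwell$beta0 + c(0, dwell$beta_activity)
  worst <- max((cap_t - mus) / sqrt(dwell$sigma_u^2 + dwell$sigma_e^2))
  if (worst < 1) {
    abort("infeasible dwell configuration: most draws exceed the session timeout (check beta/sigma)")
  }
  structure(list(n_users = n_users, seed = as.integer(seed),
                 segment_mix = segment_mix, dwell = dwell,
                 segment_behavior = segment_behavior,
                 lag_geom_prob = lag_geom_prob,
                 double_click_rate = double_click_rate,
                 single_click_user_rate = single_click_user_rate,
                 terminal_final_rate = terminal_final_rate,
                 activity_transitions = activity_transitions,
                 event_probs = event_probs,
                 covariate_effects = covariate_effects,
                 start_date = start_date, enroll_days = enroll_days,
                 horizon_days = horizon_days),
            class = "generator_config")
}

# Dwell draws are truncated to [0.011, 4.5] minutes so every within-session
# gap stays under the 300 s timeout (and above the 500 ms double-click
# threshold). The upper cap clips < 1% of draws under the default dwell
# parameters.
GEN_DWELL_CAP_MIN <- 4.5
GEN_DWELL_FLOOR_MIN <- 0.011

#' @rdname generator_config
#' @export
default_segment_behavior <- function() {
  list(A = list(p_active = 0.28, extra_sessions = 0.05, extra_clicks = 1.0),
       B = list(p_active = 0.33, extra_sessions = 1.80, extra_clicks = 2.5),
       C = list(p_active = 0.42, extra_sessions = 1.80, extra_clicks = 2.5),
       D = list(p_active = 0.30, extra_sessions = 0.05, extra_clicks = 1.0))
}

#' @rdname generator_config
#' @export
default_activity_transitions <- function() {
  m <- rbind(NAVIGATING = c(0.35, 0.60, 0.05),
             READING = c(0.25, 0.70, 0.05),
             ACCOUNT = c(0.40, 0.40, 0.20))
  colnames(m) <- ACTIVITIES
  m
}

#' @rdname generator_config
#' @export
default_event_probs <- function() {
  list(NAVIGATING = c(Search = 0.45, TOCView = 0.2, `TopicView/Outline` = 0.25,
                      SearchFacetChange = 0.1),
       READING = c(TopicView = 0.5, TopicSectionView = 0.3,
                   OfflineTopicView = 0.1, GraphicView = 0.07, PrintShare = 0.03),
       ACCOUNT = c(AccountSettings = 0.6, BookmarkAdd = 0.4))
}

#' @rdname generator_config
#' @export
default_covariate_effects <- function() {
  cb <- default_survey_codebook()
  shift0 <- function(levels) {
    m <- matrix(0, length(levels), 5, dimnames = list(levels, c("A", "B", "C", "D", "E")))
    m
  }
  age <- shift0(cb$age_group)
  age[">=35", c("A", "D", "E")] <- c(0.4, 0.4, 0.3)
  spec <- shift0(cb$specialty)
  spec["medicine", "C"] <- 0.4
  spec["emergency_medicine", "A"] <- 0.4
  region <- shift0(cb$region)
  region["sub_saharan_africa", c("C", "D")] <- 0.3
  region["europe_central_asia", "E"] <- 0.4
  dev <- shift0(cb$device_access)
  dev["low", "E"] <- 1.0
  att <- shift0(cb$clinician_attitude)
  att["positive", c("C", "E")] <- c(0.3, -0.4)
  list(
    gender = list(levels = cb$gender, base = c(0.45, 0.55), shift = shift0(cb$gender)),
    age_group = list(levels = cb$age_group, base = c(0.15, 0.50, 0.35), shift = age),
    specialty = list(levels = cb$specialty,
                     base = c(0.30, 0.12, 0.12, 0.16, 0.15, 0.15), shift = spec),
    patient_load_band = list(levels = cb$patient_load_band,
                             base = c(0.25, 0.35, 0.25, 0.15),
                             shift = shift0(cb$patient_load_band)),
    region = list(levels = cb$region, base = c(0.38, 0.22, 0.12, 0.14, 0.08, 0.06),
                  shift = region),
    device_access = list(levels = cb$device_access, base = c(0.94, 0.06), shift = dev),
    colleague_use = list(levels = cb$colleague_use, base = c(0.60, 0.40),
                         shift = shift0(cb$colleague_use)),
    clinician_attitude = list(levels = cb$clinician_attitude, base = c(0.85, 0.15),
                              shift = att),
    patient_attitude = list(levels = cb$patient_attitude, base = c(0.70, 0.30),
                            shift = shift0(cb$patient_attitude))
  )
}

# truncated normal draw by vectorized rejection (bounds far in the tail, so
# a handful of redraw passes suffice; clamps as a last resort)
rtruncnorm_vec <- function(mu, sd, lo, hi, max_pass = 50) {
  y <- rnorm(length(mu), mu, sd)
  for (i in seq_len(max_pass)) {
    bad <- y <= lo | y >= hi
    if (!any(bad)) return(y)
    y[bad] <- rnorm(sum(bad), mu[bad], sd)
  }
  pmin(pmax(y, lo + 1e-9), hi - 1e-9)
}

# transformed-scale dwell draw for given linear predictors
draw_dwell_min <- function(mu, dwell) {
  if (dwell$family == "lognormal_heavy") {
    med <- inv_boxcox(mu, dwell$lambda)
    d <- exp(log(med) + rnorm(length(mu), 0, 1.5 * dwell$sigma_e))
    return(pmin(pmax(d, GEN_DWELL_FLOOR_MIN), GEN_DWELL_CAP_MIN - 1e-6))
  }
  lo <- boxcox_transform(GEN_DWELL_FLOOR_MIN, dwell$lambda)
  hi <- boxcox_transform(GEN_DWELL_CAP_MIN, dwell$lambda)
  inv_boxcox(rtruncnorm_vec(mu, dwell$sigma_e, lo, hi), dwell$lambda)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full cohort — activation dates, latent segments, survey
#' covariates, and a clickstream with double-click artifacts and single-click
#' users injected — from a [generator_config()]. Event sequences follow a
#' Markov chain over activities starting at a Search click; inter-click gaps
#' are true activity dwell times from the Box-Cox-normal model, truncated so
#' within-session gaps stay under the 5-minute timeout. Never-users (segment
#' E) emit no clicks. The returned ground truth records each user's latent
#' segment and random intercept and every true span duration, including the
#' final spans that the pipeline sees as censored.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `clicks`, `activations`, `survey` (tibbles in the
#'   pipeline's input formats) and `truth` (list: `users`, `sessions`,
#'   `spans`), plus the `config`.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  n <- config$n_users
  users <- tibble(
    user_id = sprintf("U%05d", seq_len(n)),
    activation_date = config$start_date +
      sample.int(config$enroll_days, n, replace = TRUE) - 1L,
    segment = sample(names(config$segment_mix), n, replace = TRUE,
                     prob = config$segment_mix),
    u = rnorm(n, 0, config$dwell$sigma_u)
  )

  survey <- draw_survey(users, config$covariate_effects)

  active <- users[users$segment != "E", , drop = FALSE]
  sessions <- if (nrow(active) > 0) draw_sessions(active, config) else NULL
  spansClicks <- if (!is.null(sessions) && nrow(sessions) > 0) {
    draw_clicks(sessions, active, config)
  } else {
    list(clicks = empty_clicks(),
         spans = tibble(), sessions = tibble())
  }
  clicks <- spansClicks$clicks
  truth_spans <- spansClicks$spans
  truth_sessions <- spansClicks$sessions

  # single-click users: truncate to their first click only
  sc_ids <- character()
  if (config$single_click_user_rate > 0 && nrow(active) > 0) {
    pick <- runif(nrow(active)) < config$single_click_user_rate
    sc_ids <- active$user_id[pick]
    if (length(sc_ids) > 0) {
      firsts <- clicks |>
        filter(.data$user_id %in% sc_ids) |>
        group_by(.data$user_id) |>
        filter(row_number() == 1) |>
        ungroup()
      clicks <- bind_rows(filter(clicks, !(.data$user_id %in% sc_ids)), firsts)
      truth_spans <- filter(truth_spans, !(.data$user_id %in% sc_ids))
      truth_sessions <- filter(truth_sessions, !(.data$user_id %in% sc_ids))
    }
  }
  users$single_click <- users$user_id %in% sc_ids

  # double-click artifacts: duplicates within 500 ms of a real click
  if (config$double_click_rate > 0 && nrow(clicks) > 0) {
    dup <- runif(nrow(clicks)) < config$double_click_rate
    if (any(dup)) {
      dups <- clicks[dup, , drop = FALSE]
      dups$timestamp_ms <- dups$timestamp_ms + round(runif(nrow(dups), 50, 450))
      clicks <- bind_rows(clicks, dups)
    }
  }
  clicks <- sort_clicks(clicks)

  list(clicks = clicks,
       activations = select(users, "user_id", "activation_date"),
       survey = survey,
       truth = list(users = users, sessions = truth_sessions, spans = truth_spans),
       config = config)
}

# covariates drawn conditional on segment: level probabilities tilted by the
# per-segment log-odds shifts, keeping the marginal segment mix exact
draw_survey <- function(users, covariate_effects) {
  out <- tibble(user_id = users$user_id)
  for (cov in names(covariate_effects)) {
    spec <- covariate_effects[[cov]]
    probs <- outer(spec$base, rep(1, 5)) * exp(spec$shift)  # levels x segments
    colnames(probs) <- c("A", "B", "C", "D", "E")
    probs <- sweep(probs, 2, colSums(probs), "/")
    seg_idx <- match(users$segment, colnames(probs))
    u <- runif(nrow(users))
    cum <- apply(probs, 2, cumsum)  # levels x segments
    pick <- vapply(seq_len(nrow(users)), function(i) {
      sum(u[i] > cum[, seg_idx[i]]) + 1L
    }, integer(1))
    out[[cov]] <- spec$levels[pick]
  }
  out
}

# day-level structure: lag, period, active day offsets per user
draw_sessions <- function(active, config) {
  bh <- config$segment_behavior
  n <- nrow(active)
  longterm <- active$segment %in% c("C", "D")
  lag <- rgeom(n, config$lag_geom_prob)
  lag <- ifelse(longterm, pmin(lag, 14), pmin(lag, 60))
  period <- integer(n)
  period[longterm] <- 343L + floor(runif(sum(longterm)) *
                                     (config$horizon_days - lag[longterm] - 343L + 1))
  period[!longterm] <- 14L + floor(runif(sum(!longterm)) * (280L - 14L + 1))
  p_active <- vapply(active$segment, function(s) bh[[s]]$p_active, numeric(1))
  extra_sessions <- vapply(active$segment, function(s) bh[[s]]$extra_sessions, numeric(1))

  # active day offsets: endpoints forced, interior Bernoulli
  day_list <- lapply(seq_len(n), function(i) {
    interior <- if (period[i] > 1) {
      which(runif(period[i] - 1) < p_active[i])
    } else integer(0)
    unique(c(0L, interior, period[i]))
  })
  n_days <- lengths(day_list)
  idx <- rep(seq_len(n), n_days)
  days <- tibble(row = idx,
                 user_id = active$user_id[idx],
                 day_offset = unlist(day_list),
                 abs_day = as.numeric(active$activation_date[idx]) + lag[idx] +
                   unlist(day_list))
  # sessions per active day, capped at 4 to stay inside the day
  days$n_sess <- 1L + pmin(rpois(nrow(days), extra_sessions[days$row]), 3L)
  sidx <- rep(seq_len(nrow(days)), days$n_sess)
  slot <- unlist(lapply(days$n_sess, seq_len)) - 1L
  sessions <- tibble(
    user_id = days$user_id[sidx],
    abs_day = days$abs_day[sidx],
    start_ms = days$abs_day[sidx] * MS_PER_DAY +
      (8 + 3 * slot + runif(length(sidx))) * 3600000
  )
  arrange(sessions, .data$user_id, .data$start_ms)
}

# click sequences, true dwells, truth spans/sessions
draw_clicks <- function(sessions, active, config) {
  ns <- nrow(sessions)
  seg <- active$segment[match(sessions$user_id, active$user_id)]
  u <- active$u[match(sessions$user_id, active$user_id)]
  extra_clicks <- vapply(seg, function(s) config$segment_behavior[[s]]$extra_clicks,
                         numeric(1))
  k <- 2L + pmin(rpois(ns, extra_clicks), 13L)
  terminal <- runif(ns) < config$terminal_final_rate

  # activity chain per session, vectorized over click positions
  kmax <- max(k)
  act_idx <- matrix(NA_integer_, ns, kmax)
  act_idx[, 1] <- 1L  # NAVIGATING (sessions start at Search)
  trans <- config$activity_transitions
  cum_trans <- t(apply(trans, 1, cumsum))
  for (j in 2:kmax) {
    alive <- k >= j
    if (!any(alive)) break
    cur <- act_idx[alive, j - 1]
    r <- runif(sum(alive))
    nxt <- 1L + (r > cum_trans[cur, 1]) + (r > cum_trans[cur, 2])
    act_idx[alive, j] <- nxt
  }

  sess_id <- rep(seq_len(ns), k)
  click_pos <- sequence(k)
  activity <- ACTIVITIES[act_idx[cbind(sess_id, click_pos)]]

  # event types: Search for the opening click, otherwise sampled within
  # activity
  event <- character(length(activity))
  event[click_pos == 1] <- "Search"
  for (a in ACTIVITIES) {
    sel <- click_pos > 1 & activity == a
    if (any(sel)) {
      ep <- config$event_probs[[a]]
      event[sel] <- sample(names(ep), sum(sel), replace = TRUE, prob = ep)
    }
  }

  # true dwells: click i engages its activity for dwell_i minutes
  mu <- config$dwell$beta0 +
    ifelse(activity == "READING", config$dwell$beta_activity[["READING"]],
           ifelse(activity == "ACCOUNT", config$dwell$beta_activity[["ACCOUNT"]], 0)) +
    u[sess_id]
  dwell_min <- draw_dwell_min(mu, config$dwell)

  # cumulative dwell before each click, reset at session starts
  base <- cumsum(dwell_min) - dwell_min
  start_rel <- base - rep(base[click_pos == 1], k)
  ts <- sessions$start_ms[sess_id] + start_rel * MS_PER_MIN

  clicks <- tibble(user_id = sessions$user_id[sess_id],
                   timestamp_ms = round(ts),
                   event_type = event)
  # terminal-ended sessions get a closing external-link click
  if (any(terminal)) {
    last_idx <- cumsum(k)
    tsel <- which(terminal)
    term_clicks <- tibble(
      user_id = sessions$user_id[tsel],
      timestamp_ms = round(ts[last_idx[tsel]] + dwell_min[last_idx[tsel]] * MS_PER_MIN),
      event_type = "ExternalLinkClick")
    clicks <- bind_rows(clicks, term_clicks)
  }
  clicks <- sort_clicks(clicks)

  spans <- tibble(user_id = sessions$user_id[sess_id],
                  session_id = sess_id,
                  span_index = click_pos,
                  activity = activity,
                  start_ms = round(ts),
                  true_duration_min = dwell_min,
                  end_ms = round(ts + dwell_min * MS_PER_MIN),
                  censored_in_pipeline = click_pos == k[sess_id] & !terminal[sess_id])

  truth_sessions <- spans |>
    group_by(.data$user_id, .data$session_id) |>
    summarise(start_ms = min(.data$start_ms),
              end_ms = max(.data$end_ms),
              n_clicks = n(),
              navigating_min = sum(.data$true_duration_min[.data$activity == "NAVIGATING"]),
              reading_min = sum(.data$true_duration_min[.data$activity == "READING"]),
              account_min = sum(.data$true_duration_min[.data$activity == "ACCOUNT"]),
              .groups = "drop") |>
    mutate(duration_min = (.data$end_ms - .data$start_ms) / MS_PER_MIN,
           terminal_end = terminal[.data$session_id]) |>
    arrange(.data$user_id, .data$start_ms) |>
    group_by(.data$user_id) |>
    mutate(session_index = row_number()) |>
    ungroup()

  # last click of a non-terminal session is the censored span's start
  last_click <- spans |>
    group_by(.data$session_id) |>
    summarise(lc = max(.data$start_ms), .groups = "drop")
  truth_sessions$last_click_ms <- ifelse(
    truth_sessions$terminal_end, truth_sessions$end_ms,
    last_click$lc[match(truth_sessions$session_id, last_click$session_id)])

  spans$session_index <- truth_sessions$session_index[
    match(spans$session_id, truth_sessions$session_id)]

  list(clicks = clicks,
       spans = select(spans, -"session_id"),
       sessions = select(truth_sessions, -"session_id"))
}

#' Draw spans directly from the dwell model
#'
#' Generates known-duration spans straight from the Box-Cox-normal mixed
#' model (no session structure, no truncation), for parameter-recovery
#' validation of [fit_duration_model()] and [estimate_lambda()].
#'
#' @param n_users Number of users.
#' @param spans_per_user Spans per user.
#' @param params A [dwell_params()] object.
#' @param seed Integer seed.
#' @param activity_probs Sampling probabilities of the three activities.
#' @return List with `spans` (tibble `user_id`, `activity`, `duration_min`,
#'   `duration_known = TRUE`) and `truth` (list with the generating
#'   parameters and per-user intercepts).
#' @export
simulate_spans <- function(n_users = 300, spans_per_user = 40,
                           params = dwell_params(), seed = 1,
                           activity_probs = c(NAVIGATING = 0.45, READING = 0.45,
                                              ACCOUNT = 0.10)) {
  set.seed(as.integer(seed))
  u <- rnorm(n_users, 0, params$sigma_u)
  N <- n_users * spans_per_user
  uid <- rep(sprintf("U%05d", seq_len(n_users)), each = spans_per_user)
  activity <- sample(names(activity_probs), N, replace = TRUE, prob = activity_probs)
  offs <- ifelse(activity == "READING", params$beta_activity[["READING"]],
                 ifelse(activity == "ACCOUNT", params$beta_activity[["ACCOUNT"]], 0))
  mu <- params$beta0 + offs + rep(u, each = spans_per_user)
  y <- rnorm(N, mu, params$sigma_e)
  dur <- inv_boxcox(y, params$lambda)
  list(spans = tibble(user_id = uid, activity = activity,
                      duration_min = dur, duration_known = TRUE),
       truth = list(params = params,
                    user_intercepts = tibble(user_id = sprintf("U%05d", seq_len(n_users)),
                                             u = u)))
}

#' Simulate a confounded segment/survey table
#'
#' Generates segment labels and two covariates where the exposure is
#' associated with the segment only through a binary confounder: the
#' confounder shifts both the exposure distribution and the segment odds,
#' while conditionally on it the exposure carries no effect (unless
#' `direct_effect` is nonzero). Used to validate that marginal
#' standardization removes confounding.
#'
#' @param n Number of users.
#' @param seed Integer seed.
#' @param confounder_effect Log-odds shift of heavy/long segments for
#'   confounder level "z1".
#' @param direct_effect Additional log-odds shift applied directly by the
#'   exposure (0 = pure confounding).
#' @return Tibble `user_id`, `segment`, `exposure`, `confounder`.
#' @export
simulate_confounded_survey <- function(n = 4000, seed = 1,
                                       confounder_effect = 1.2,
                                       direct_effect = 0) {
  set.seed(as.integer(seed))
  z <- sample(c("z0", "z1"), n, replace = TRUE)
  # exposure depends strongly on the confounder
  p_x <- ifelse(z == "z1", 0.8, 0.2)
  x <- ifelse(runif(n) < p_x, "exposed", "unexposed")
  base <- log(c(A = 0.25, B = 0.15, C = 0.24, D = 0.21, E = 0.15))
  seg <- vapply(seq_len(n), function(i) {
    lp <- base
    if (z[i] == "z1") lp[c("B", "C")] <- lp[c("B", "C")] + confounder_effect
    if (x[i] == "exposed") lp[c("B", "C")] <- lp[c("B", "C")] + direct_effect
    p <- exp(lp) / sum(exp(lp))
    sample(names(p), 1, prob = p)
  }, character(1))
  tibble(user_id = sprintf("U%05d", seq_len(n)),
         segment = factor(seg, levels = names(segment_labels())),
         exposure = x, confounder = z)
}

#' Write a generated cohort to CSV files
#'
#' Emits the three CSVs the pipeline ingests (`clicks.csv`,
#' `activations.csv`, `survey.csv`) plus ground-truth tables
#' (`truth_users.csv`, `truth_sessions.csv`, `truth_spans.csv`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$clicks, file.path(dir, "clicks.csv"))
  readr::write_csv(cohort$activations, file.path(dir, "activations.csv"))
  readr::write_csv(cohort$survey, file.path(dir, "survey.csv"))
  readr::write_csv(cohort$truth$users, file.path(dir, "truth_users.csv"))
  if (nrow(cohort$truth$sessions) > 0) {
    readr::write_csv(cohort$truth$sessions, file.path(dir, "truth_sessions.csv"))
    readr::write_csv(cohort$truth$spans, file.path(dir, "truth_spans.csv"))
  }
  invisible(dir)
}
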