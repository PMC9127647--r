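#' Read a clickstream log
#'
#' Reads a delimited clickstream export with one row per click and returns the
#' parsed records sorted per user by timestamp. Three columns are required:
#' an opaque user identifier, a timestamp, and an event-type token. Timestamps
#' may be given either as epoch milliseconds (UTC) or as ISO-8601 date-times
#' with fractional seconds; the dialect is controlled by `timestamp_format`.
#'
#' Rows whose timestamp cannot be parsed, or with an empty user id or event
#' type, are rejected and counted rather than silently dropped. Ties in
#' timestamp are broken by event type (lexicographic), then input order, so
#' downstream processing is reproducible.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_user,col_time,col_event Column names holding the user id,
#'   timestamp and event type (defaults `"user_id"`, `"timestamp_ms"`,
#'   `"event_type"`).
#' @param timestamp_format `"epoch_ms"` (default) or `"iso8601"`.
#' @param delim Field delimiter (default `","`).
#' @return A list with elements `clicks` (tibble with columns `user_id`,
#'   `timestamp_ms`, `event_type`, sorted), `n_parsed` and `n_rejected`.
#' @export
read_clickstream <- function(path,
                             col_user = "user_id",
                             col_time = "timestamp_ms",
                             col_event = "event_type",
                             timestamp_format = c("epoch_ms", "iso8601"),
                             delim = ",") {
  timestamp_format <- match.arg(timestamp_format)
  if (!file.exists(path)) {
    abort(sprintf("clickstream file not found: %s", path))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c(col_user, col_time, col_event), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("clickstream file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  n_in <- nrow(raw)
  if (n_in == 0) {
    return(list(clicks = empty_clicks(), n_parsed = 0L, n_rejected = 0L))
  }
  ts <- parse_click_timestamp(raw[[col_time]], timestamp_format)
  user <- raw[[col_user]]
  event <- raw[[col_event]]
  ok <- !is.na(ts) & !is.na(user) & nzchar(user) & !is.na(event) & nzchar(event) & ts >= 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("rejected %d malformed clickstream row(s)", n_rejected))
  }
  clicks <- tibble(user_id = user[ok], timestamp_ms = ts[ok], event_type = event[ok])
  list(clicks = sort_clicks(clicks), n_parsed = nrow(clicks), n_rejected = n_rejected)
}

parse_click_timestamp <- function(x, timestamp_format) {
  if (timestamp_format == "epoch_ms") {
    suppressWarnings(as.numeric(x))
  } else {
    t <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    round(as.numeric(t) * 1000)
  }
}

empty_clicks <- function() {
  tibble(user_id = character(), timestamp_ms = numeric(), event_type = character())
}

#' Sort click records into canonical order
#'
#' Stable sort by user, then timestamp, then event type; input order breaks
#' remaining ties (the sort is stable).
#'
#' @param clicks Tibble with `user_id`, `timestamp_ms`, `event_type`.
#' @return The sorted tibble.
#' @export
sort_clicks <- function(clicks) {
  arrange(clicks, .data$user_id, .data$timestamp_ms, .data$event_type)
}

#' Remove double clicks
#'
#' Scans each user's clicks forward in time and removes any click that occurs
#' less than `threshold_ms` after the most recent *retained* click of the same
#' user (keep-first rule). After filtering, all same-user inter-click gaps are
#' at least `threshold_ms`. The rule is applied per user and ignores event
#' type.
#'
#' @param clicks Tibble of clicks sorted per user by timestamp (see
#'   [sort_clicks()]).
#' @param threshold_ms Minimum allowed gap in milliseconds (default 500).
#' @return A list with `clicks` (filtered tibble, still sorted) and
#'   `n_removed`.
#' @export
remove_double_clicks <- function(clicks, threshold_ms = 500) {
  stopifnot(threshold_ms > 0)
  if (nrow(clicks) == 0) {
    return(list(clicks = clicks, n_removed = 0L))
  }
  keep <- keep_after_dedup(clicks$user_id, clicks$timestamp_ms, threshold_ms)
  list(clicks = clicks[keep, , drop = FALSE], n_removed = sum(!keep))
}

# Forward scan anchored on the last retained click of each user: a click is
# dropped when it falls within threshold_ms of the retained anchor; retained
# clicks move the anchor. Sequential by nature (each decision depends on the
# previous retention), so a single explicit pass.
keep_after_dedup <- function(user, ts, threshold_ms) {
  n <- length(ts)
  keep <- logical(n)
  last_user <- NA_character_
  anchor <- -Inf
  for (i in seq_len(n)) {
    ui <- user[i]
    if (is.na(last_user) || ui != last_user) {
      last_user <- ui
      anchor <- -Inf
    }
    if (ts[i] - anchor < threshold_ms) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      anchor <- ts[i]
    }
  }
  keep
}

#' Exclude users with exactly one click
#'
#' Users left with a single click after double-click removal carry no usable
#' interaction signal; they are removed from the clickstream and reported so
#' that segmentation can treat them as never-users.
#'
#' @param clicks Filtered click tibble.
#' @return A list with `clicks` (users with >= 2 clicks) and
#'   `excluded_user_ids` (character vector).
#' @export
drop_single_click_users <- function(clicks) {
  if (nrow(clicks) == 0) {
    return(list(clicks = clicks, excluded_user_ids = character()))
  }
  tab <- table(clicks$user_id)
  singles <- names(tab)[tab == 1]
  list(clicks = clicks[!(clicks$user_id %in% singles), , drop = FALSE],
       excluded_user_ids = singles)
}

#' Default event-type to activity mapping
#'
#' The mapping classifies each vendor event type into one of three activities
#' (navigating, reading, account management) or marks it as terminal.
#' Navigating covers searches and movement toward content; reading covers
#' exposure to medical content including printing/sharing/offline views;
#' account covers settings and bookmarks; terminal events (external link
#' clicks) end activity and never open a span.
#'
#' @return Tibble with columns `event_type` and `activity`.
#' @export
default_activity_map <- function() {
  tibble(
    event_type = c("Search", "TOCView", "TopicView/Outline", "SearchFacetChange",
                   "TopicView", "TopicSectionView", "OfflineTopicView",
                   "GraphicView", "PrintShare",
                   "AccountSettings", "BookmarkAdd",
                   "ExternalLinkClick"),
    activity = c(rep("NAVIGATING", 4),
                 rep("READING", 5),
                 rep("ACCOUNT", 2),
                 "TERMINAL")
  )
}

#' Construct a validated activity map
#'
#' @param mapping Tibble with columns `event_type`, `activity`; activities
#'   must be among NAVIGATING, READING, ACCOUNT, TERMINAL.
#' @param unknown_policy What to do with an event type absent from the map:
#'   `"error"` (default; abort naming the token), `"drop"` (discard the
#'   click), or `"navigating"` (treat as navigating).
#' @return An object of class `activity_map`.
#' @export
activity_map <- function(mapping = default_activity_map(),
                         unknown_policy = c("error", "drop", "navigating")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(all(c("event_type", "activity") %in% names(mapping)))
  bad <- setdiff(unique(mapping$activity), ACTIVITY_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown activity class(es) in map: %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(mapping$event_type)) {
    abort("duplicate event types in activity map")
  }
  structure(list(mapping = as_tibble(mapping[c("event_type", "activity")]),
                 unknown_policy = unknown_policy),
            class = "activity_map")
}

#' Read an activity map from a CSV file
#'
#' @param path CSV with columns `event_type`, `activity`.
#' @inheritParams activity_map
#' @return An `activity_map` object.
#' @export
read_activity_map <- function(path, unknown_policy = c("error", "drop", "navigating")) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  activity_map(m, match.arg(unknown_policy))
}

#' Classify event types into activities
#'
#' @param event_type Character vector of event-type tokens.
#' @param map An [activity_map()].
#' @return Character vector of activity classes (NA for unknown types under
#'   policy `"drop"`).
#' @export
classify_event <- function(event_type, map = activity_map()) {
  stopifnot(inherits(map, "activity_map"))
  idx <- match(event_type, map$mapping$event_type)
  act <- map$mapping$activity[idx]
  unknown <- is.na(idx)
  if (any(unknown)) {
    if (map$unknown_policy == "error") {
      abort(sprintf("unmapped event type(s): %s",
                    paste(unique(event_type[unknown]), collapse = ", ")))
    } else if (map$unknown_policy == "navigating") {
      act[unknown] <- "NAVIGATING"
    }  # "drop": leave NA, caller removes
  }
  act
}

#' Attach an activity column to a click tibble
#'
#' Applies [classify_event()] and, under the `"drop"` policy, removes clicks
#' with unmapped event types.
#'
#' @param clicks Click tibble.
#' @param map An [activity_map()].
#' @return The click tibble with an `activity` column.
#' @export
classify_clicks <- function(clicks, map = activity_map()) {
  clicks$activity <- classify_event(clicks$event_type, map)
  dropped <- is.na(clicks$activity)
  if (any(dropped)) {
    warn(sprintf("dropped %d click(s) with unmapped event types", sum(dropped)))
    clicks <- clicks[!dropped, , drop = FALSE]
  }
  clicks
}

#' Read the activation table
#'
#' One row per enrolled user giving the date the subscription activation email
#' was sent.
#'
#' @param path CSV with columns `user_id`, `activation_date` (ISO-8601 date).
#' @return Tibble with `user_id` (character) and `activation_date` (Date).
#' @export
read_activations <- function(path) {
  a <- readr::read_csv(path, col_types = readr::cols(
    user_id = "c", activation_date = readr::col_date()
  ), progress = FALSE, show_col_types = FALSE)
  if (anyDuplicated(a$user_id)) abort("duplicate user_id in activation table")
  if (any(is.na(a$activation_date))) abort("unparseable activation_date")
  as_tibble(a)
}

#' Read the baseline survey table
#'
#' @param path CSV with a `user_id` column plus covariate columns.
#' @param codebook Optional named list of allowed levels per covariate (as
#'   from [default_survey_codebook()]); when given, values outside the
#'   vocabulary raise an error (closed vocabularies).
#' @return Tibble of survey responses.
#' @export
read_survey <- function(path, codebook = NULL) {
  s <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  if (!"user_id" %in% names(s)) abort("survey table must have a user_id column")
  if (anyDuplicated(s$user_id)) abort("duplicate user_id in survey table")
  if (!is.null(codebook)) validate_survey(s, codebook)
  as_tibble(s)
}

validate_survey <- function(survey, codebook) {
  for (cov in intersect(names(codebook), names(survey))) {
    vals <- survey[[cov]]
    bad <- setdiff(unique(vals[!is.na(vals)]), codebook[[cov]])
    if (length(bad) > 0) {
      abort(sprintf("survey column '%s' has value(s) outside its vocabulary: %s",
                    cov, paste(bad, collapse = ", ")))
    }
  }
  invisible(survey)
}
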