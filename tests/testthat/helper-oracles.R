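# Independent brute-force references used across test files. These are
# deliberately naive (explicit loops, no shared code with the package
# internals beyond exported constructors).

# keep-first double-click removal, one user at a time
oracle_dedup <- function(ts, threshold_ms = 500) {
  keep <- logical(length(ts))
  anchor <- -Inf
  for (i in seq_along(ts)) {
    if (ts[i] - anchor >= threshold_ms) {
      keep[i] <- TRUE
      anchor <- ts[i]
    }
  }
  keep
}

# timeout sessionizer for one user: returns session id per click and a
# data.frame of spans (activity, start, end or NA)
oracle_sessionize <- function(ts, activity, timeout_ms = 300000) {
  n <- length(ts)
  sid <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (i == 1 || ts[i] - ts[i - 1] >= timeout_ms) cur <- cur + 1L
    sid[i] <- cur
  }
  spans <- list()
  for (s in unique(sid)) {
    idx <- which(sid == s)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (activity[i] == "TERMINAL") next
      end <- if (j < length(idx)) ts[idx[j + 1]] else NA_real_
      spans[[length(spans) + 1]] <- data.frame(
        session = s, activity = activity[i], start = ts[i], end = end)
    }
  }
  list(session_id = sid,
       spans = if (length(spans)) do.call(rbind, spans) else
         data.frame(session = integer(), activity = character(),
                    start = numeric(), end = numeric()))
}

# inter-click gaps straddling the 300 s timeout, including the exact boundary
random_gaps <- function(n, p_break = 0.25) {
  breaks <- runif(n) < p_break
  g <- numeric(n)
  g[breaks] <- sample(c(300000, 300001, 450000, 600000), sum(breaks), replace = TRUE)
  g[!breaks] <- sample(c(600, 1000, 299999), sum(!breaks), replace = TRUE)
  g
}

random_activities <- function(n, p_terminal = 0.08) {
  acts <- c("NAVIGATING", "READING", "ACCOUNT")
  a <- sample(acts, n, replace = TRUE)
  a[runif(n) < p_terminal] <- "TERMINAL"
  a
}

# clicks tibble for one user from gaps/activities (event_type chosen to match
# the activity under the default map)
clicks_from_gaps <- function(user, gaps, activity, base_ms = 1.5e12) {
  ev <- c(NAVIGATING = "Search", READING = "TopicView",
          ACCOUNT = "AccountSettings", TERMINAL = "ExternalLinkClick")
  tibble::tibble(user_id = user,
                 timestamp_ms = base_ms + cumsum(c(0, gaps)),
                 event_type = unname(ev[activity]),
                 activity = activity)
}
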