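test_that("a 5-minute gap splits clicks into sessions (four-click example)", {
  fx <- scripted_fixture("fig2_session")
  s <- build_sessions(fx$clicks)
  expect_equal(s$summary$n_sessions, fx$expected$n_sessions)
  expect_equal(s$sessions$click_count, fx$expected$session_sizes)
  known <- s$spans[s$spans$duration_known, ]
  expect_equal(known$duration_min, fx$expected$known_span_min)
  expect_equal(sum(!s$spans$duration_known), fx$expected$n_censored)
})

test_that("the final non-terminal click opens a censored span", {
  cl <- clicks_from_gaps("U1", 60000, c("NAVIGATING", "READING"))
  s <- build_sessions(cl)
  expect_equal(nrow(s$spans), 2L)
  expect_equal(s$spans$activity, c("NAVIGATING", "READING"))
  expect_equal(s$spans$duration_min[1], 1)
  expect_false(s$spans$duration_known[2])
  expect_true(is.na(s$spans$end_ms[2]))
})

test_that("a terminal final click closes the session with nothing censored", {
  fx <- scripted_fixture("terminal_final")
  s <- build_sessions(fx$clicks)
  expect_equal(s$summary$n_sessions, 1L)
  expect_equal(sum(!s$spans$duration_known), 0L)
  expect_equal(setNames(s$spans$duration_min, s$spans$activity),
               fx$expected$span_min)
  expect_true(s$sessions$terminal_end)
  expect_equal((s$sessions$end_ms - s$sessions$start_ms) / 60000,
               fx$expected$session_duration_min)
})

test_that("an intra-session terminal click closes the preceding span without opening one", {
  cl <- clicks_from_gaps("U1", c(30000, 60000),
                         c("NAVIGATING", "TERMINAL", "READING"))
  s <- build_sessions(cl)
  # one session; NAVIGATING span closed at the terminal click; READING censored
  expect_equal(s$summary$n_sessions, 1L)
  expect_equal(nrow(s$spans), 2L)
  expect_equal(s$spans$activity, c("NAVIGATING", "READING"))
  expect_equal(s$spans$duration_min[1], 0.5)
  expect_false(s$spans$duration_known[2])
})

test_that("session boundaries are exact at the timeout threshold", {
  fx <- scripted_fixture("boundary_300s")
  s <- build_sessions(fx$clicks)
  counts <- table(s$sessions$user_id)
  expect_equal(as.integer(counts[["U1"]]), 2L)  # gap == 300 s: new session
  expect_equal(as.integer(counts[["U2"]]), 1L)  # gap == 300 s - 1 ms: same
})

test_that("a terminal-only session is discarded and counted", {
  cl <- dplyr::bind_rows(
    clicks_from_gaps("U1", c(30000, 400000), c("NAVIGATING", "READING", "TERMINAL")),
    clicks_from_gaps("U2", 30000, c("NAVIGATING", "READING")))
  s <- build_sessions(cl)
  expect_equal(s$summary$n_discarded_terminal_sessions, 1L)
  expect_equal(s$summary$n_sessions, 2L)
})

test_that("sessionizer matches the brute-force splitter on random instances", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(2:120, 1)
    gaps <- random_gaps(n - 1)
    acts <- random_activities(n)
    cl <- clicks_from_gaps("U1", gaps, acts)
    s <- build_sessions(cl)
    o <- oracle_sessionize(cl$timestamp_ms, cl$activity)
    # compare spans on non-degenerate sessions (oracle keeps terminal-only
    # sessions; the package discards them)
    o_spans <- o$spans
    expect_equal(nrow(s$spans), nrow(o_spans))
    if (nrow(o_spans) > 0) {
      expect_equal(s$spans$start_ms, o_spans$start)
      expect_equal(s$spans$end_ms, o_spans$end)
      expect_equal(s$spans$activity, o_spans$activity)
    }
  }
})

test_that("every retained click belongs to exactly one session (partition)", {
  set.seed(203)
  n <- 400
  cl <- clicks_from_gaps("U1", random_gaps(n - 1), random_activities(n, 0))
  s <- build_sessions(cl)
  expect_equal(sum(s$sessions$click_count), n)
  # concatenating sessions reproduces input order
  expect_equal(s$spans$start_ms, sort(s$spans$start_ms))
  # all internal gaps < timeout, all cross-session gaps >= timeout
  sid <- rep(seq_len(nrow(s$sessions)), s$sessions$click_count)
  gaps <- diff(cl$timestamp_ms)
  same <- sid[-1] == sid[-length(sid)]
  expect_true(all(gaps[same] < 300000))
  expect_true(all(gaps[!same] >= 300000))
})

test_that("observed time is conserved: known span minutes equal intra-session gaps", {
  set.seed(204)
  n <- 300
  cl <- clicks_from_gaps("U1", random_gaps(n - 1), random_activities(n, 0))
  s <- build_sessions(cl)
  sid <- rep(seq_len(nrow(s$sessions)), s$sessions$click_count)
  gaps <- diff(cl$timestamp_ms)
  intra <- sum(gaps[sid[-1] == sid[-length(sid)]])
  expect_equal(sum(s$spans$duration_min[s$spans$duration_known]) * 60000, intra)
})

test_that("degenerate inputs sessionize cleanly", {
  s0 <- build_sessions(clicks_from_gaps("U1", numeric(0), "NAVIGATING")[0, ])
  expect_equal(s0$summary$n_sessions, 0L)
  # all gaps under the timeout: exactly one session
  cl <- clicks_from_gaps("U1", rep(1000, 9), random_activities(10, 0))
  expect_equal(build_sessions(cl)$summary$n_sessions, 1L)
  # unclassified clicks are rejected
  bad <- tibble::tibble(user_id = "U1", timestamp_ms = c(0, 1000),
                        event_type = "Search")
  expect_error(build_sessions(bad), "activity")
})
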