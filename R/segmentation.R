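#' Segment cut points
#'
#' The two binary cut points defining the behavioral segments: a user is
#' *heavy* when their rate of use is at least `heavy_rate_min` minutes per
#' active day (default 5, a round number near the observed median rate), and
#' *long-term* when their period of use is at least `longterm_weeks` weeks
#' (default 48, roughly the full subscription year). Both boundaries are
#' inclusive; 48 weeks is taken as exactly 336 days with no calendar
#' alignment.
#'
#' @param heavy_rate_min Minutes per active day at or above which use is
#'   heavy.
#' @param longterm_weeks Weeks of period-of-use at or above which use is
#'   long-term.
#' @return Object of class `segment_thresholds`.
#' @export
segment_thresholds <- function(heavy_rate_min = 5, longterm_weeks = 48) {
  stopifnot(heavy_rate_min > 0, longterm_weeks > 0)
  structure(list(heavy_rate_min = heavy_rate_min,
                 longterm_weeks = longterm_weeks,
                 longterm_days = ceiling(longterm_weeks * 7)),
            class = "segment_thresholds")
}

#' Segment labels and their names
#'
#' @return Named character vector mapping labels A-E to descriptive names.
#' @export
segment_labels <- function() {
  c(A = "short-term light", B = "short-term heavy",
    C = "long-term heavy", D = "long-term light", E = "never-user")
}

#' Assign behavioral segments
#'
#' Maps each usage profile to one of five segments: never-users (no retained
#' clicks, including single-click-excluded users) are segment E; otherwise the
#' heavy and long-term indicators place the user in A (short-term light),
#' B (short-term heavy), C (long-term heavy) or D (long-term light).
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @param thresholds A [segment_thresholds()] object.
#' @return `profiles` with added columns `is_longterm`, `is_heavy`, `segment`
#'   (factor A-E) and `segment_name`.
#' @export
assign_segments <- function(profiles, thresholds = segment_thresholds()) {
  stopifnot(inherits(thresholds, "segment_thresholds"))
  lt <- profiles$ever_user & profiles$period_days >= thresholds$longterm_days
  hv <- profiles$ever_user & profiles$rate_min_per_active_day >= thresholds$heavy_rate_min
  seg <- ifelse(!profiles$ever_user, "E",
                ifelse(lt, ifelse(hv, "C", "D"), ifelse(hv, "B", "A")))
  profiles |>
    mutate(is_longterm = ifelse(.data$ever_user, lt, NA),
           is_heavy = ifelse(.data$ever_user, hv, NA),
           segment = factor(seg, levels = names(segment_labels())),
           segment_name = unname(segment_labels()[seg]))
}

#' Cohort segment distribution
#'
#' @param segments Tibble with a `segment` column (from [assign_segments()]).
#' @return Tibble with one row per segment: `segment`, `segment_name`, `n`,
#'   `pct` (shares sum to 100).
#' @export
segment_cohort <- function(segments) {
  stopifnot("segment" %in% names(segments))
  tab <- table(factor(segments$segment, levels = names(segment_labels())))
  out <- tibble(segment = names(tab),
                segment_name = unname(segment_labels()[names(tab)]),
                n = as.integer(tab),
                pct = 100 * as.integer(tab) / max(1, sum(tab)))
  if (sum(out$n) != nrow(segments)) abort("segment counts do not conserve cohort size")
  out
}
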