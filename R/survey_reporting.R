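#' Default survey codebook
#'
#' Closed level vocabularies for the baseline survey covariates: demographics
#' (gender, age group, specialty, patient load, region), device access, and
#' three professional-climate items.
#'
#' @return Named list of allowed levels per covariate.
#' @export
default_survey_codebook <- function() {
  list(
    gender = c("female", "male"),
    age_group = c("<25", "25-34", ">=35"),
    specialty = c("medicine", "emergency_medicine", "ob_gyn", "surgery",
                  "pediatrics", "other"),
    patient_load_band = c("<50", "50-99", "100-199", ">=200"),
    region = c("sub_saharan_africa", "south_asia", "southeast_asia",
               "latin_america", "middle_east_north_africa", "europe_central_asia"),
    device_access = c("high", "low"),
    colleague_use = c(">=half", "<half"),
    clinician_attitude = c("positive", "other"),
    patient_attitude = c("positive", "neutral_negative_variable")
  )
}

#' Cross-tabulate segments by a survey covariate
#'
#' Joins segment assignments to survey responses and tabulates raw counts and
#' row percentages of the five segments per covariate level. Complete-case:
#' users missing the covariate (or absent from the survey) are dropped and
#' counted.
#'
#' @param segments Tibble with `user_id` and `segment`.
#' @param survey Survey tibble with `user_id` and covariate columns.
#' @param covariate Covariate column name.
#' @return A tibble of class `segment_crosstab` (long format: `level`,
#'   `segment`, `n`, `pct`), with attributes `covariate`, `n_unmatched`
#'   (segmented users not in the survey) and `n_missing` (missing covariate
#'   values).
#' @export
join_and_tabulate <- function(segments, survey, covariate) {
  if (!covariate %in% names(survey)) {
    abort(sprintf("unknown covariate: %s", covariate))
  }
  joined <- inner_join(select(segments, "user_id", "segment"),
                       select(survey, "user_id", all_of(covariate)),
                       by = "user_id")
  n_unmatched <- nrow(segments) - nrow(joined)
  miss <- is.na(joined[[covariate]])
  n_missing <- sum(miss)
  joined <- joined[!miss, , drop = FALSE]
  if (nrow(joined) == 0) {
    warn(sprintf("no complete cases for covariate '%s'", covariate))
  }
  tab <- joined |>
    count(level = .data[[covariate]],
          segment = factor(.data$segment, levels = names(segment_labels())),
          .drop = FALSE) |>
    group_by(.data$level) |>
    mutate(pct = 100 * .data$n / max(1, sum(.data$n))) |>
    ungroup()
  structure(tab, class = c("segment_crosstab", class(tab)),
            covariate = covariate, n_unmatched = n_unmatched,
            n_missing = n_missing)
}

#' Covariate-adjusted segment distributions
#'
#' Fits a multinomial logistic regression of segment on an exposure covariate
#' plus adjusters, then reports marginally standardized segment percentages:
#' for each exposure level, every complete-case user's segment probabilities
#' are predicted with their own adjuster values but the exposure set to that
#' level, and averaged. With an empty adjuster set the marginal
#' standardization reduces algebraically to the raw row percentages, which
#' are then returned directly (exact, no fitting noise). No hypothesis tests
#' are produced.
#'
#' @param segments Tibble with `user_id`, `segment`.
#' @param survey Survey tibble.
#' @param exposure Name of the exposure covariate (>= 2 observed levels).
#' @param adjusters Character vector of adjuster covariate names (possibly
#'   empty).
#' @return Tibble `level`, `segment`, `adjusted_pct` (per level, sums to
#'   100), with attribute `n_complete`.
#' @export
adjusted_distribution <- function(segments, survey, exposure, adjusters = character()) {
  vars <- c(exposure, adjusters)
  missing_vars <- setdiff(vars, names(survey))
  if (length(missing_vars) > 0) {
    abort(sprintf("covariate(s) not in survey: %s", paste(missing_vars, collapse = ", ")))
  }
  dat <- inner_join(select(segments, "user_id", "segment"),
                    select(survey, "user_id", all_of(vars)), by = "user_id")
  dat <- dat[complete.cases(dat), , drop = FALSE]
  lv <- unique(dat[[exposure]])
  if (length(lv) < 2) abort("exposure must have at least 2 observed levels")

  if (length(adjusters) == 0) {
    ct <- join_and_tabulate(segments, survey, exposure)
    out <- tibble(level = ct$level, segment = as.character(ct$segment),
                  adjusted_pct = ct$pct)
    attr(out, "n_complete") <- nrow(dat)
    return(out)
  }

  check_sparse_cells(dat, exposure, adjusters)
  # largest segment as reference; predictions invariant to this
  seg_tab <- sort(table(dat$segment), decreasing = TRUE)
  dat$segment <- stats::relevel(factor(dat$segment, levels = names(segment_labels())[
    names(segment_labels()) %in% dat$segment]), ref = names(seg_tab)[1])
  for (v in vars) dat[[v]] <- factor(dat[[v]])
  fml <- stats::as.formula(paste("segment ~", paste(vars, collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500)
  if (fit$convergence != 0) warn("multinomial model did not fully converge")

  seg_levels <- levels(dat$segment)
  res <- lapply(sort(levels(dat[[exposure]])), function(l) {
    nd <- dat
    nd[[exposure]] <- factor(l, levels = levels(dat[[exposure]]))
    p <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p, deparse.level = 0)  # 2-segment case
    colnames(p) <- seg_levels
    tibble(level = l, segment = seg_levels, adjusted_pct = 100 * colMeans(p))
  })
  out <- bind_rows(res) |> arrange(.data$level, .data$segment)
  attr(out, "n_complete") <- nrow(dat)
  out
}

check_sparse_cells <- function(dat, exposure, adjusters) {
  for (v in c(exposure, adjusters)) {
    tab <- table(dat[[v]], dat$segment)
    if (any(rowSums(tab) == 0)) next
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)
      warn(sprintf("sparse cells (zero counts) for '%s' x segment: %d empty cell(s); estimates may be unstable",
                   v, nrow(empty)))
    }
  }
  invisible(dat)
}

#' Write a segment-by-covariate report bundle
#'
#' Produces one raw crosstab CSV per covariate, optional adjusted-distribution
#' CSVs, and a JSON manifest. The report contains counts and percentages
#' only — no hypothesis tests.
#'
#' @param segments Tibble with `user_id`, `segment`.
#' @param survey Survey tibble.
#' @param covariates Covariate names to tabulate.
#' @param adjusters Adjuster set for the adjusted distributions; `NULL` skips
#'   adjustment.
#' @param out_dir Output directory (created if needed).
#' @return The manifest (invisibly), a list describing the written tables.
#' @export
report_segments <- function(segments, survey, covariates,
                            adjusters = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(covariates = covariates, tables = list(),
                   n_users = nrow(segments))
  if (length(covariates) == 0 || nrow(segments) == 0) {
    warn("empty report: no covariates or no segmented users")
  }
  for (cov in covariates) {
    ct <- join_and_tabulate(segments, survey, cov)
    f <- file.path(out_dir, paste0("crosstab_", cov, ".csv"))
    readr::write_csv(as_tibble(ct), f)
    entry <- list(covariate = cov, raw_table = basename(f),
                  n_unmatched = attr(ct, "n_unmatched"),
                  n_missing = attr(ct, "n_missing"))
    if (!is.null(adjusters) && nrow(segments) > 0 &&
        length(setdiff(adjusters, cov)) > 0) {
      adj <- adjusted_distribution(segments, survey, cov, setdiff(adjusters, cov))
      fa <- file.path(out_dir, paste0("adjusted_", cov, ".csv"))
      readr::write_csv(adj, fa)
      entry$adjusted_table <- basename(fa)
      entry$adjusters <- setdiff(adjusters, cov)
    }
    manifest$tables[[cov]] <- entry
  }
  jsonlite::write_json(manifest, file.path(out_dir, "report_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Stacked-bar plot of segment distributions
#'
#' @param crosstab A `segment_crosstab` from [join_and_tabulate()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_segment_distribution <- function(crosstab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(as_tibble(crosstab),
                  ggplot2::aes(x = .data$level, y = .data$pct, fill = .data$segment)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = attr(crosstab, "covariate"), y = "% of users",
                  fill = "Segment") +
    ggplot2::theme_minimal()
}
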