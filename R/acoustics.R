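# Acoustic group-comparison pipeline: low-frequency energy ratio, snoring
# frequency and event duration per patient, Mann-Whitney group tests, and
# the exclusion sensitivity analysis.

#' Low-frequency energy ratio of a segment
#'
#' Fraction of Welch-PSD energy below the cutoff (default 650 Hz) relative
#' to the total up to Nyquist, with trapezoidal integration and the cutoff
#' interpolated exactly. Invariant to overall amplitude scaling.
#'
#' @param segment An `audio_segment`, cohort segment, `audio_signal`, or
#'   numeric waveform.
#' @param cutoff_hz Band edge in Hz (default 650).
#' @param sample_rate Sample rate when `segment` is a bare numeric vector.
#' @return Ratio in \[0, 1\]; `NA` (with a warning) for an all-zero segment.
#' @export
lf_energy_ratio <- function(segment, cutoff_hz = 650, sample_rate = SNORE_SR) {
  if (is.list(segment)) {
    x <- if (!is.null(segment$samples)) segment$samples else segment$wave
    if (!is.null(segment$sample_rate)) sample_rate <- segment$sample_rate
  } else {
    x <- as.numeric(segment)
  }
  if (all(x == 0)) {
    warning("all-zero segment: low-frequency energy ratio undefined")
    return(NA_real_)
  }
  w <- welch_psd(x, sample_rate)
  band_energy_fraction(w$freq, w$psd, cutoff_hz)
}

#' Per-patient acoustic summary
#'
#' The patient-level indicators: median low-frequency energy ratio over the
#' patient's snore segments, event count normalized to an 8-hour recording,
#' and median event duration.
#'
#' @param patient_id Patient identifier.
#' @param group Group label.
#' @param lfer_values Per-snore-segment LFER values (may be empty).
#' @param events Data frame with a `duration_s` column (or `start_s`/`end_s`).
#' @param recording_hours Actual recording length in hours (default 8).
#' @return One-row data frame with `patient_id`, `group`, `lfer`,
#'   `events_per_8h`, `duration_median_s`; missing indicators are `NA`.
#' @export
summarize_patient <- function(patient_id, group, lfer_values, events,
                              recording_hours = 8) {
  stopifnot(recording_hours > 0)
  if (!is.null(events) && nrow(events) > 0 && is.null(events$duration_s)) {
    events$duration_s <- events$end_s - events$start_s
  }
  lfer <- if (length(lfer_values) > 0 && any(!is.na(lfer_values))) {
    stats::median(lfer_values, na.rm = TRUE)
  } else NA_real_
  n_ev <- if (is.null(events)) 0L else nrow(events)
  data.frame(patient_id = patient_id, group = group, lfer = lfer,
             events_per_8h = if (n_ev > 0) n_ev * 8 / recording_hours else NA_real_,
             duration_median_s = if (n_ev > 0) stats::median(events$duration_s) else NA_real_)
}

#' Acoustic summaries for a whole synthetic cohort
#'
#' @param cohort A `snore_cohort`.
#' @param measure_audio If `TRUE`, compute each snore segment's LFER from its
#'   waveform with [lf_energy_ratio()]; otherwise use the generator's
#'   per-segment values directly (fast path for Monte-Carlo studies).
#' @return Data frame of per-patient summaries.
#' @export
cohort_acoustic_summaries <- function(cohort, measure_audio = FALSE) {
  stopifnot(inherits(cohort, "snore_cohort"))
  hrs <- cohort$spec$recording_hours
  do.call(rbind, lapply(cohort$patients, function(p) {
    lfer_vals <- if (measure_audio) {
      snore <- Filter(function(s) s$label == 1L, p$segments)
      vapply(snore, function(s) {
        lf_energy_ratio(s$wave, sample_rate = cohort$spec$sample_rate)
      }, numeric(1))
    } else {
      p$segment_lfer
    }
    if (length(lfer_vals) == 0) lfer_vals <- p$lfer  # fall back to patient truth
    summarize_patient(p$patient_id, p$group, lfer_vals, p$events,
                      recording_hours = hrs)
  }))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided. Without ties and with `min(n) <= 8` the exact U distribution
#' is used; otherwise the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction (the convention of mainstream
#' statistics software). The standardized statistic Z is negative when group
#' A tends to rank lower than group B.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param variable Optional variable name carried into the result.
#' @return Object of class `group_test`: `U`, `Z`, `p`, `significant`
#'   (p < 0.05), `method`, group medians and IQRs.
#' @export
mann_whitney <- function(a, b, variable = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group in Mann-Whitney test")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  mu <- n1 * n2 / 2
  N <- n1 + n2
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  cc <- if (U1 > mu) 0.5 else if (U1 < mu) -0.5 else 0
  Z <- if (sigma > 0) (U1 - mu - cc) / sigma else 0
  if (!has_ties && min(n1, n2) <= 8) {
    p <- if (U1 > mu) 2 * (1 - stats::pwilcox(U1 - 1, n1, n2))
         else 2 * stats::pwilcox(U1, n1, n2)
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(Z)) else 1
    method <- "normal approximation (tie-corrected)"
  }
  iqr_fmt <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(variable = variable, U = U1, Z = Z, p = p,
                 significant = p < 0.05, method = method,
                 n = c(n1, n2),
                 median_a = stats::median(a), median_b = stats::median(b),
                 iqr_a = iqr_fmt(a), iqr_b = iqr_fmt(b)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: median %.3f (%.3f-%.3f) vs %.3f (%.3f-%.3f), U=%.1f Z=%.3f p=%.4g%s [%s]\n",
              ifelse(is.na(x$variable), "group test", x$variable),
              x$median_a, x$iqr_a[1], x$iqr_a[2],
              x$median_b, x$iqr_b[1], x$iqr_b[2],
              x$U, x$Z, x$p, ifelse(x$significant, " *", ""), x$method))
  invisible(x)
}

#' Group comparison of the three acoustic indicators
#'
#' Mann-Whitney tests of LFER, snoring frequency (events/8 h) and median
#' event duration between the stenotic (group A) and non-stenotic (group B)
#' patients of a summary table.
#'
#' @param summaries Data frame from [cohort_acoustic_summaries()] /
#'   [summarize_patient()] with `group` in `{stenotic, non_stenotic}`.
#' @return Named list of three `group_test` results (`lfer`, `frequency`,
#'   `duration`).
#' @export
group_comparison <- function(summaries) {
  stopifnot(all(c("group", "lfer", "events_per_8h", "duration_median_s")
                %in% names(summaries)))
  ga <- summaries[summaries$group == "stenotic", ]
  gb <- summaries[summaries$group == "non_stenotic", ]
  if (nrow(ga) == 0 || nrow(gb) == 0) stop("a group has no patients")
  list(
    lfer = mann_whitney(ga$lfer, gb$lfer, "low-frequency energy ratio"),
    frequency = mann_whitney(ga$events_per_8h, gb$events_per_8h,
                             "snoring frequency (events/8 h)"),
    duration = mann_whitney(ga$duration_median_s, gb$duration_median_s,
                            "snoring event duration (s)"))
}

#' Sensitivity analysis excluding flagged patients
#'
#' Re-runs [group_comparison()] on the subset with the flagged patients
#' removed (e.g. those with comorbid cerebral infarction/ischemia), and
#' reports the new group sizes.
#'
#' @param summaries Summary table as in [group_comparison()].
#' @param exclude_ids Patient IDs to drop (empty set allowed).
#' @return List with `tests` (as [group_comparison()]) and `group_sizes`.
#' @export
sensitivity_excluding <- function(summaries, exclude_ids = character(0)) {
  kept <- summaries[!(summaries$patient_id %in% exclude_ids), ]
  sizes <- c(stenotic = sum(kept$group == "stenotic"),
             non_stenotic = sum(kept$group == "non_stenotic"))
  if (any(sizes == 0)) stop("exclusion removed an entire group")
  list(tests = group_comparison(kept), group_sizes = sizes)
}

#' Baseline demographic comparisons
#'
#' Standard two-group tests for a baseline-characteristics table:
#' independent-samples t-test for continuous variables, chi-square (or
#' Fisher's exact when any expected cell count is below 5) for categorical
#' variables.
#'
#' @param df Data frame with a `group` column.
#' @param continuous Names of continuous columns.
#' @param categorical Names of categorical columns.
#' @return Data frame with `variable`, `test`, `statistic`, `p`.
#' @export
demographic_tests <- function(df, continuous = character(0),
                              categorical = character(0)) {
  stopifnot("group" %in% names(df))
  rows <- list()
  for (v in continuous) {
    ht <- stats::t.test(df[[v]] ~ df$group, var.equal = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "t", statistic = unname(ht$statistic), p = ht$p.value)
  }
  for (v in categorical) {
    tab <- table(df[[v]], df$group)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- stats::fisher.test(tab)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, test = "fisher", statistic = NA_real_, p = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, test = "chisq", statistic = unname(ht$statistic),
        p = ht$p.value)
    }
  }
  do.call(rbind, rows)
}
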