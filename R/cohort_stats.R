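#' Gaussian-distribution check
#'
#' One-sample Kolmogorov-Smirnov test of a sample against a normal
#' distribution with the sample's own mean and SD (the Lilliefors caveat —
#' estimated parameters make the nominal KS p-value conservative — is
#' accepted as the field convention). A degenerate (constant) sample is
#' reported as non-normal.
#'
#' @param values Numeric sample, n >= 5.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` when the sample is compatible with normality
#'   (p >= `alpha`), else `FALSE`.
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values for a normality check")
  s <- stats::sd(values)
  if (s == 0) return(FALSE)
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  p >= alpha
}

# "mean +/- SD" or "median [Q1-Q3]" presentation, following each arm's own
# normality flag
present_arm <- function(values) {
  normal <- length(values) >= 5 && normality_check(values)
  if (normal) {
    list(style = "mean_sd",
         text = sprintf("%.4g ± %.4g", mean(values), stats::sd(values)),
         mean = mean(values), sd = stats::sd(values))
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    list(style = "median_iqr",
         text = sprintf("%.4g [%.4g–%.4g]", q[2], q[1], q[3]),
         median = q[2], q1 = q[1], q3 = q[3])
  }
}

#' Paired baseline/intervention comparison
#'
#' Reproduces the standard paired-comparison workflow: pairwise-complete
#' values, a normality gate on the pairwise *differences* (paired t-test when
#' normal, Wilcoxon matched-pairs signed-rank test otherwise), and each arm
#' presented by its own normality flag (mean +/- SD, or median with 25th-75th
#' percentiles). All-zero differences are reported as "no difference"
#' (p = 1), since neither test statistic is defined there.
#'
#' @param baseline,intervention Numeric vectors of paired measurements (same
#'   length, matched by position).
#' @param metric Label carried into the report.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return Object of class `paired_report`: `metric`, `n`, `test`,
#'   `statistic`, `p_value`, `normal_diffs`, `baseline`, `intervention`
#'   (presentation lists), `mean_diff`.
#' @export
paired_compare <- function(baseline, intervention, metric = "",
                           alpha = 0.05) {
  if (length(baseline) != length(intervention)) {
    stop("baseline and intervention must be paired (equal length)")
  }
  ok <- is.finite(baseline) & is.finite(intervention)
  b <- baseline[ok]; i <- intervention[ok]
  if (length(b) < 3) stop("need at least 3 complete pairs")
  d <- i - b
  if (all(d == 0)) {
    res <- list(test = "none", statistic = NA_real_, p_value = 1,
                normal_diffs = NA)
  } else if (length(d) >= 5 && stats::sd(d) > 0 && normality_check(d, alpha)) {
    # below 5 pairs the normality gate cannot run; fall through to the
    # distribution-free test
    tt <- stats::t.test(i, b, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, normal_diffs = TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(i, b, paired = TRUE))
    res <- list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
                p_value = wt$p.value, normal_diffs = FALSE)
  }
  structure(c(list(metric = metric, n = length(b)), res,
              list(baseline = present_arm(b), intervention = present_arm(i),
                   mean_diff = mean(d))),
            class = "paired_report")
}

#' @export
print.paired_report <- function(x, ...) {
  cat(sprintf("<paired_report> %s (n = %d)\n",
              if (nzchar(x$metric)) x$metric else "metric", x$n))
  cat(sprintf("  baseline:     %s\n", x$baseline$text))
  cat(sprintf("  intervention: %s\n", x$intervention$text))
  cat(sprintf("  %s: p = %.4g\n", x$test, x$p_value))
  invisible(x)
}

#' Classification-flip bookkeeping between paired conditions
#'
#' Counts how many paired measurements cross a classification cutoff between
#' baseline and intervention — e.g. Mx crossing 0.3 (intact/impaired
#' autoregulation) or band coherence crossing 0.34 (unreliable/reliable
#' transfer-function read-out). Values strictly above the cutoff are in the
#' `high` state.
#'
#' @param baseline,intervention Paired numeric values.
#' @param cutoff Classification threshold.
#' @param labels Named character vector `c(low = ..., high = ...)` naming the
#'   two states (default intact/impaired).
#' @param metric Label carried into the table.
#' @return Object of class `flip_table`: `metric`, `cutoff`, `labels`,
#'   `n_total`, `n_to_high` (low at baseline, high at intervention),
#'   `n_to_low`, `n_unchanged`.
#' @export
flip_count <- function(baseline, intervention, cutoff,
                       labels = c(low = "intact", high = "impaired"),
                       metric = "") {
  if (length(baseline) != length(intervention)) {
    stop("baseline and intervention must be paired (equal length)")
  }
  ok <- is.finite(baseline) & is.finite(intervention)
  b_high <- baseline[ok] > cutoff
  i_high <- intervention[ok] > cutoff
  structure(list(metric = metric, cutoff = cutoff, labels = labels,
                 n_total = sum(ok),
                 n_to_high = sum(!b_high & i_high),
                 n_to_low = sum(b_high & !i_high),
                 n_unchanged = sum(b_high == i_high)),
            class = "flip_table")
}

#' @export
print.flip_table <- function(x, ...) {
  cat(sprintf("<flip_table> %s at cutoff %g (n = %d)\n",
              if (nzchar(x$metric)) x$metric else "metric",
              x$cutoff, x$n_total))
  cat(sprintf("  %s -> %s: %d\n", x$labels[["low"]], x$labels[["high"]],
              x$n_to_high))
  cat(sprintf("  %s -> %s: %d\n", x$labels[["high"]], x$labels[["low"]],
              x$n_to_low))
  cat(sprintf("  unchanged: %d\n", x$n_unchanged))
  invisible(x)
}

#' Cohort-level report from a per-segment summary table
#'
#' Takes the per-record summary produced by [cmd_analyze()] (one row per
#' analyzed record, identified by `subject`, `timepoint`, `condition`),
#' pairs baselines with interventions, and produces paired comparisons for
#' every metric plus flip tables for Mx (intact/impaired at 0.3) and band
#' coherence (unreliable/reliable at 0.34).
#'
#' @param summary_df Data frame with columns `subject`, `timepoint`,
#'   `condition` and metric columns (`cv_map`, `cv_mfv`, `mx`, `coh_vlf`,
#'   `gain_vlf`, `phase_vlf`, `coh_lf`, `gain_lf`, `phase_lf`).
#' @param mx_cutoff Mx classification cutoff (default 0.3).
#' @param coherence_cutoff Reliability cutoff (default 0.34).
#' @return List with `comparisons` (named list of `paired_report`s),
#'   `flips` (named list of `flip_table`s), and `pairs` (the paired wide
#'   table).
#' @export
cohort_report <- function(summary_df, mx_cutoff = 0.3,
                          coherence_cutoff = 0.34) {
  need <- c("subject", "timepoint", "condition")
  if (!all(need %in% names(summary_df))) {
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  }
  metrics <- intersect(
    c("cv_map", "cv_mfv", "mx", "coh_vlf", "gain_vlf", "phase_vlf",
      "coh_lf", "gain_lf", "phase_lf"),
    names(summary_df))
  base <- summary_df[summary_df$condition == "baseline", , drop = FALSE]
  intv <- summary_df[summary_df$condition == "intervention", , drop = FALSE]
  key <- function(df) paste(df$subject, df$timepoint, sep = "/")
  common <- intersect(key(base), key(intv))
  if (length(common) < 3) stop("need at least 3 complete baseline/intervention pairs")
  base <- base[match(common, key(base)), , drop = FALSE]
  intv <- intv[match(common, key(intv)), , drop = FALSE]
  comparisons <- lapply(metrics, function(m) {
    paired_compare(base[[m]], intv[[m]], metric = m)
  })
  names(comparisons) <- metrics
  flips <- list()
  if ("mx" %in% metrics) {
    flips$mx <- flip_count(base$mx, intv$mx, mx_cutoff,
                           labels = c(low = "intact", high = "impaired"),
                           metric = "mx")
  }
  for (m in intersect(c("coh_vlf", "coh_lf"), metrics)) {
    flips[[m]] <- flip_count(base[[m]], intv[[m]], coherence_cutoff,
                             labels = c(low = "unreliable", high = "reliable"),
                             metric = m)
  }
  pairs <- data.frame(subject = base$subject, timepoint = base$timepoint)
  for (m in metrics) {
    pairs[[paste0(m, "_baseline")]] <- base[[m]]
    pairs[[paste0(m, "_intervention")]] <- intv[[m]]
  }
  list(comparisons = comparisons, flips = flips, pairs = pairs)
}
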