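# Normality-gated two-group comparisons: Shapiro-Wilk on each sample decides
# between the unpaired t test (both normal) and the Mann-Whitney U test.
# Two-tailed throughout, alpha = 0.05, no multiple-testing correction (each
# morphometric row is tested on its own, as is conventional for these
# reports; the absence of correction is recorded in the table metadata).

#' Shapiro-Wilk normality gate for a two-group comparison
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 3 values and
#'   non-zero variance.
#' @return List with `both_normal` (logical: Shapiro-Wilk p > 0.05 in both
#'   samples), `p_a`, `p_b`.
#' @export
normality_gate <- function(sample_a, sample_b) {
  for (s in list(a = sample_a, b = sample_b)) {
    if (length(s) < 3) stop2("normality gate needs n >= 3 per group")
    if (length(unique(s)) == 1)
      stop2("constant sample: normality test undefined")
  }
  p_a <- stats::shapiro.test(sample_a)$p.value
  p_b <- stats::shapiro.test(sample_b)$p.value
  list(both_normal = p_a > 0.05 && p_b > 0.05, p_a = p_a, p_b = p_b)
}

summary_mean_sem <- function(x) {
  sprintf("%.3g (+/- %.3g)", mean(x), stats::sd(x) / sqrt(length(x)))
}

summary_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
}

#' Two-group comparison with the normality-gated test choice
#'
#' Both samples normal (per [normality_gate()]): two-sided unpaired t test,
#' equal-variance form by default (`var_equal = FALSE` switches to the
#' Welch form; the choice is recorded). Otherwise: two-sided Mann-Whitney U,
#' exact when the combined sample size is at most 20 and there are no ties,
#' normal approximation with tie correction otherwise. Group summaries
#' follow the convention: mean (+/- SEM) for normal data, median (Q1-Q3)
#' otherwise.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param gate Optional precomputed [normality_gate()] result (or a logical
#'   `both_normal` to force a branch).
#' @param metric Label for the compared quantity.
#' @param var_equal Use the equal-variance t statistic (default `TRUE`).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return One-row data frame of class `group_comparison`: `metric`, `n_a`,
#'   `n_b`, `summary_a`, `summary_b`, `test` (`"t"` or `"U"`), `statistic`,
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(sample_a, sample_b, gate = NULL, metric = "metric",
                           var_equal = TRUE, alpha = 0.05) {
  if (is.null(gate)) gate <- normality_gate(sample_a, sample_b)
  if (is.logical(gate)) gate <- list(both_normal = gate)
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1)
    stop2("constant data in both groups: comparison undefined")
  identical_groups <- length(sample_a) == length(sample_b) &&
    all(sort(sample_a) == sort(sample_b))
  if (gate$both_normal) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal,
                        alternative = "two.sided")
    test <- "t"
    stat <- unname(ht$statistic)
    p <- ht$p.value
    sa <- summary_mean_sem(sample_a)
    sb <- summary_mean_sem(sample_b)
  } else {
    n <- length(sample_a) + length(sample_b)
    exact <- n <= 20 && !any(duplicated(pooled))
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = exact,
                         correct = TRUE, alternative = "two.sided"))
    test <- "U"
    stat <- unname(ht$statistic) # R's W for x,y is the Mann-Whitney U
    p <- ht$p.value
    if (is.nan(p)) p <- if (identical_groups) 1 else NA_real_
    sa <- summary_median_iqr(sample_a)
    sb <- summary_median_iqr(sample_b)
  }
  out <- data.frame(metric = metric,
                    n_a = length(sample_a), n_b = length(sample_b),
                    summary_a = sa, summary_b = sb,
                    test = test, statistic = stat, p_value = p,
                    significant = !is.na(p) && p < alpha)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Metric-by-metric comparison table for two cohorts
#'
#' Builds a morphometry comparison table: one normality-gated two-group test
#' per metric column, applied to the per-cell values of the two cohorts. The
#' gate is evaluated per metric (so a table can mix t and U rows). Cohorts
#' must have been analysed with identical classification criteria; mismatched
#' criteria are refused. Rows whose data are degenerate (fewer than 3 finite
#' values per group, or a constant sample, where Shapiro-Wilk is undefined)
#' fall back to the nonparametric branch, or report `NA` when no test is
#' possible.
#'
#' @param cohort_a,cohort_b `ol_cohort` objects from [analyze_swc_dir()] (or
#'   data frames of per-cell metrics carrying a `criteria` attribute).
#' @param metrics Character vector of metric columns to compare; defaults to
#'   the standard morphometry panel present in both cohorts.
#' @param var_equal,alpha Passed to [compare_groups()].
#' @return Data frame with one `group_comparison` row per metric; attributes
#'   `criteria`, `alpha` and `p_adjust` (`"none"`) record provenance.
#' @export
report_table <- function(cohort_a, cohort_b, metrics = NULL,
                         var_equal = TRUE, alpha = 0.05) {
  ca <- if (inherits(cohort_a, "ol_cohort")) cohort_a$cells else cohort_a
  cb <- if (inherits(cohort_b, "ol_cohort")) cohort_b$cells else cohort_b
  crit_a <- attr(ca, "criteria")
  crit_b <- attr(cb, "criteria")
  if (!is.null(crit_a) && !is.null(crit_b) &&
      !identical(unclass(crit_a), unclass(crit_b)))
    stop2("cohorts were analysed with different internode criteria; ",
          "re-analyse with a shared configuration before comparing")
  if (nrow(ca) < 3 || nrow(cb) < 3)
    stop2("normality gate needs n >= 3 cells per cohort")
  if (is.null(metrics)) {
    panel <- c("arbor_count", "mean_arbor_length_um", "total_branches",
               "max_branch_order", "internode_count",
               "mean_internode_length_um", "median_internode_length_um",
               "min_initiation_order", "max_initiation_order",
               "mean_initiation_order", "max_internodes_per_arbor",
               "nm_pb_over_tb", "m_pb_over_tb")
    metrics <- intersect(panel, intersect(names(ca), names(cb)))
  }
  rows <- lapply(metrics, function(m) {
    a <- ca[[m]][is.finite(ca[[m]])]
    b <- cb[[m]][is.finite(cb[[m]])]
    gate <- tryCatch(normality_gate(a, b), error = function(e) NULL)
    if (is.null(gate)) {
      # Shapiro-Wilk undefined (constant sample or n < 3): nonparametric
      # fallback when testable, NA row otherwise
      if (length(a) >= 3 && length(b) >= 3 &&
          length(unique(c(a, b))) > 1) {
        gate <- list(both_normal = FALSE)
      } else {
        return(data.frame(metric = m, n_a = length(a), n_b = length(b),
                          summary_a = if (length(a)) summary_median_iqr(a) else NA,
                          summary_b = if (length(b)) summary_median_iqr(b) else NA,
                          test = "none", statistic = NA_real_,
                          p_value = NA_real_, significant = NA))
      }
    }
    compare_groups(a, b, gate = gate, metric = m,
                   var_equal = var_equal, alpha = alpha)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    class(r) <- "data.frame"
    r
  }))
  rownames(out) <- NULL
  attr(out, "criteria") <- crit_a %||% crit_b
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- "none"
  out
}

#' Write a comparison table with provenance
#'
#' Emits the table as CSV plus a JSON sidecar recording the classification
#' criteria, alpha, and that no multiple-testing correction was applied.
#'
#' @param table Result of [report_table()].
#' @param prefix Output path prefix.
#' @return Files written, invisibly.
#' @export
write_report <- function(table, prefix) {
  files <- c(table = paste0(prefix, "_comparison.csv"),
             meta = paste0(prefix, "_comparison_meta.json"))
  utils::write.csv(table, files["table"], row.names = FALSE)
  meta <- list(alpha = attr(table, "alpha"),
               p_adjust = attr(table, "p_adjust"),
               criteria = unclass(attr(table, "criteria")))
  jsonlite::write_json(meta, files["meta"], auto_unbox = TRUE)
  invisible(files)
}
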