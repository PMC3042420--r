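# Cohort statistics: mean +/- SEM summaries, Student t tests and the
# condition-summary report.

.metric_cols <- c("I_m100_pA", "g_minus_nS", "Vr_mV", "I_p100_pA",
                  "g_plus_nS")

#' Mean and standard error of a metric across cells
#'
#' @param values Numeric vector, length >= 2.
#' @return A `"condition_summary"` list: `mean`, `sem` (sd/sqrt(n)), `n`.
#' @export
summarize_metric <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for a SEM")
  structure(list(mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values)),
                 n = length(values)),
            class = "condition_summary")
}

#' Student t test with significance mark
#'
#' Classical Student t test (two-sided; unpaired tests pool variances —
#' `welch = TRUE` switches to the Welch correction). Returns the Table-style
#' significance mark: the double-dagger for p < `alpha`, `"ns"` otherwise.
#' Paired samples whose differences have zero variance are degenerate for
#' the t statistic; a nonzero constant difference is reported as p = 0 with
#' a note, a zero difference as t = 0, p = 1.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired or unpaired comparison.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch correction for unpaired tests.
#' @return A `"comparison_result"` list: `t`, `p`, `df`, `paired`, `mark`,
#'   `note`.
#' @export
metric_t_test <- function(a, b, paired = TRUE, alpha = 0.05,
                          welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  if (paired && length(a) != length(b))
    stop("paired test requires equal sample lengths")
  note <- NULL
  if (paired && stats::sd(a - b) == 0) {
    d <- mean(a - b)
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
    note <- "zero-variance paired differences"
    df <- length(a) - 1
  } else {
    ht <- stats::t.test(a, b, paired = paired,
                        var.equal = !welch || paired)
    t <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  structure(list(t = t, p = p, df = df, paired = paired,
                 mark = if (p < alpha) "‡" else "ns", note = note),
            class = "comparison_result")
}

# default condition comparisons for the canonical series designs
.default_comparisons <- function(conds, series_id) {
  pairs <- list()
  if (all(c("control", "benzamil") %in% conds))
    pairs[[length(pairs) + 1L]] <- c("control", "benzamil")
  for (lab in conds) {
    dr <- paste0(lab, "+benz")
    if (dr %in% conds) pairs[[length(pairs) + 1L]] <- c(lab, dr)
  }
  if (all(c("Na.wash", "Na+benz") %in% conds))
    pairs[[length(pairs) + 1L]] <- c("Na.wash", "Na+benz")
  if (all(c("Na+benz", "NMDG") %in% conds))
    pairs[[length(pairs) + 1L]] <- c("Na+benz", "NMDG")
  if (series_id == 4 && all(c("Na", "Li") %in% conds))
    pairs[[length(pairs) + 1L]] <- c("Na", "Li")
  unique(pairs)
}

#' Build a condition-summary report for one or more cohorts
#'
#' Aggregates per-cell metrics into mean +/- SEM (n) per condition and
#' applies paired Student t tests between the conditions of each series arm
#' (control vs drug, pre vs post substitution), attaching the
#' double-dagger/ns mark per metric. The input is the (row-bound) output of
#' [cohort_metrics()] over one or more series.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @param comparisons Optional data.frame with columns `series`, `arm`,
#'   `condition_a`, `condition_b`, `paired`; defaults to the canonical
#'   design comparisons.
#' @param alpha Significance level for the mark.
#' @return A `"summary_table"` list with data.frames `summary` (per
#'   series/arm/condition/metric: mean, sem, n) and `comparisons` (per
#'   compared pair and metric: t, p, mark).
#' @export
build_summary_table <- function(metrics, comparisons = NULL, alpha = 0.05) {
  if (nrow(metrics) == 0) stop("empty metrics table")
  sum_rows <- list(); cmp_rows <- list()
  for (key in unique(paste(metrics$series, metrics$arm, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    ser <- as.numeric(parts[1]); arm <- parts[2]
    m <- metrics[metrics$series == ser & metrics$arm == arm, ]
    conds <- unique(m$condition)
    for (cond in conds) {
      mc <- m[m$condition == cond, ]
      for (met in .metric_cols) {
        if (nrow(mc) < 2) next
        s <- summarize_metric(mc[[met]])
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          series = ser, arm = arm, condition = cond, metric = met,
          mean = s$mean, sem = s$sem, n = s$n, stringsAsFactors = FALSE)
      }
    }
    pairs <- if (is.null(comparisons)) .default_comparisons(conds, ser) else {
      cc <- comparisons[comparisons$series == ser & comparisons$arm == arm, ]
      lapply(seq_len(nrow(cc)), function(i)
        c(cc$condition_a[i], cc$condition_b[i]))
    }
    for (pr in pairs) {
      ca <- m[m$condition == pr[1], ]; cb <- m[m$condition == pr[2], ]
      common <- intersect(ca$cell, cb$cell)
      if (length(common) < 2) next
      ca <- ca[match(common, ca$cell), ]; cb <- cb[match(common, cb$cell), ]
      for (met in .metric_cols) {
        ht <- metric_t_test(ca[[met]], cb[[met]], paired = TRUE,
                            alpha = alpha)
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          series = ser, arm = arm, condition_a = pr[1], condition_b = pr[2],
          metric = met, t = ht$t, p = ht$p, paired = TRUE, mark = ht$mark,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 comparisons = do.call(rbind, cmp_rows)),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Condition summaries (mean ± SEM (n)):\n")
  s <- x$summary
  for (key in unique(paste(s$series, s$arm, s$condition))) {
    rows <- s[paste(s$series, s$arm, s$condition) == key, ]
    cat(sprintf("  S%-2s %-8s %-10s ", rows$series[1], rows$arm[1],
                rows$condition[1]))
    cat(paste(sprintf("%s=%.4g±%.3g(%d)", sub("_.*", "", rows$metric),
                      rows$mean, rows$sem, rows$n), collapse = "  "), "\n")
  }
  if (!is.null(x$comparisons)) {
    cat("Comparisons (paired Student t, two-sided):\n")
    c2 <- x$comparisons
    for (i in seq_len(nrow(c2)))
      cat(sprintf("  S%-2s %-8s %s vs %s  %-10s t=%7.2f  p=%.3g  %s\n",
                  c2$series[i], c2$arm[i], c2$condition_a[i],
                  c2$condition_b[i], c2$metric[i], c2$t[i], c2$p[i],
                  c2$mark[i]))
  }
  invisible(x)
}

#' Write a summary table to CSV / JSON
#'
#' @param x A `"summary_table"`.
#' @param stem Output path stem: writes `<stem>_summary.csv`,
#'   `<stem>_comparisons.csv` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_summary_table <- function(x, stem) {
  utils::write.csv(x$summary, paste0(stem, "_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(x$comparisons, paste0(stem, "_comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = x$summary,
                            comparisons = x$comparisons),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
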