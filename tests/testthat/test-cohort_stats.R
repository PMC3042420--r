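# Cohort summaries and Student t tests.

test_that("summarize_metric computes mean and SEM", {
  s <- summarize_metric(c(5, 5, 5))
  expect_equal(s$mean, 5); expect_equal(s$sem, 0); expect_equal(s$n, 3)
  s2 <- summarize_metric(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_error(summarize_metric(5), "at least 2")
  # sem scales linearly
  x <- c(1.2, 5.3, 2.2, 9)
  expect_equal(summarize_metric(3 * x)$sem, 3 * summarize_metric(x)$sem)
})

test_that("t tests match the textbook formulas and mark significance", {
  a <- c(1, 2, 3)
  r <- metric_t_test(a, a, paired = TRUE)
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$mark, "ns")
  # constant nonzero paired difference: degenerate variance, significant
  r2 <- metric_t_test(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_lt(r2$p, 0.05)
  expect_match(r2$note, "zero-variance")
  # direct-formula oracle, paired and unpaired
  withr::with_seed(202, {
    for (i in 1:20) {
      x <- rnorm(6); y <- rnorm(6, 0.5)
      d <- x - y
      t_paired <- mean(d) / (sd(d) / sqrt(length(d)))
      expect_equal(metric_t_test(x, y, paired = TRUE)$t, t_paired,
                   tolerance = 1e-10)
      sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                   (length(x) + length(y) - 2))
      t_unp <- (mean(x) - mean(y)) /
        (sp * sqrt(1 / length(x) + 1 / length(y)))
      expect_equal(metric_t_test(x, y, paired = FALSE)$t, t_unp,
                   tolerance = 1e-10)
      # invariance under a common affine shift of both paired arms
      expect_equal(metric_t_test(2 * x + 7, 2 * y + 7, paired = TRUE)$t,
                   metric_t_test(x, y, paired = TRUE)$t, tolerance = 1e-10)
    }
  })
  expect_error(metric_t_test(1:3, 1:4, paired = TRUE), "equal")
})

test_that("summary table keeps cohort bookkeeping and tolerates missing
           conditions", {
  mk <- function(cond, vals)
    data.frame(series = 2, arm = "Na", cell = seq_along(vals),
               condition = cond, Vr_mV = 0, I_m100_pA = vals,
               I_p100_pA = -vals, g_minus_nS = 10, g_plus_nS = 10)
  metrics <- rbind(mk("control", c(-2000, -2100, -1900, -2050)),
                   mk("benzamil", c(-250, -280, -240, -260)))
  st <- build_summary_table(metrics)
  s <- st$summary
  expect_true(all(s$n == 4))
  expect_equal(sort(unique(s$condition)), c("benzamil", "control"))
  cmp <- st$comparisons
  expect_true(all(cmp$paired))
  expect_equal(cmp$mark[cmp$metric == "I_m100_pA"], "‡")
  # control-only cohort: summaries but no comparisons
  st2 <- build_summary_table(mk("control", c(-2000, -2100, -1900)))
  expect_null(st2$comparisons)
  expect_error(build_summary_table(metrics[0, ]), "empty")
})
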