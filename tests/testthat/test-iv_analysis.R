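# Sweep extraction, steady-state averaging, voltage corrections and I-V
# metrics.

test_that("sweep extraction finds complete sweeps and drops truncated ones", {
  b <- quick_bundle(duration_s = 22)   # 4 complete sweeps (5.3 s repeat)
  s <- extract_sweeps(b)
  expect_equal(length(unique(s$sweep)), 4)
  expect_equal(nrow(s), 4 * 11)
  # truncate mid-sweep: the cut sweep is dropped
  cut <- which(b$time_s < 5.3 + 1.0)
  b_cut <- b
  for (f in c("time_s", "current_pA", "command_mV", "sweep", "step_mV"))
    b_cut[[f]] <- b_cut[[f]][cut]
  expect_message(s_cut <- extract_sweeps(b_cut), "dropped")
  expect_equal(length(unique(s_cut$sweep)), 1)
  # reconstruction from command edges matches annotation-based extraction
  b_anon <- b
  b_anon$sweep <- rep(NA_integer_, length(b$sweep))
  s2 <- extract_sweeps(b_anon)
  expect_equal(s2$i_start, s$i_start)
  expect_equal(s2$step_mV, s$step_mV)
  # a bundle with no complete sweep warns and returns an empty set
  b_none <- b
  keep <- which(b$time_s < 0.5)
  for (f in c("time_s", "current_pA", "command_mV", "sweep", "step_mV"))
    b_none[[f]] <- b_none[[f]][keep]
  expect_warning(s0 <- suppressMessages(extract_sweeps(b_none)),
                 "no complete sweep")
  expect_equal(nrow(s0), 0)
})

test_that("steady-state window sits at [end-32, end-2] ms and averages
           exactly", {
  fs <- 5000
  const <- rep(100, 0.3 * fs)
  r <- steady_state_mean(const, fs)
  expect_equal(r$I_mean_pA, 100)
  expect_equal(r$I_sd_pA, 0)
  expect_equal(r$n_samples, 150)
  # analytic decaying exponential: window mean approaches the asymptote
  t <- seq(0, 0.3 - 1 / fs, by = 1 / fs)
  A <- 50; B <- 400
  slice <- A + B * exp(-t / 0.005)
  r <- steady_state_mean(slice, fs)
  expect_equal(r$I_mean_pA, A, tolerance = 1e-3 * B)
  # window placement on a 200 ms step: samples covering 168-198 ms
  marker <- numeric(0.2 * fs)
  idx_expected <- (0.168 * fs + 1):(0.198 * fs)
  marker[idx_expected] <- 1
  expect_equal(steady_state_mean(marker, fs)$I_mean_pA, 1)
  expect_error(steady_state_mean(rep(1, 100), fs), "shorter")
})

test_that("voltage correction applies ljp and the pipette voltage drop", {
  pts <- data.frame(V_cmd_mV = c(-100, 0, 100), I_pA = c(-2000, 0, 2000))
  expect_equal(correct_voltages(pts)$V_mV, pts$V_cmd_mV)
  expect_equal(correct_voltages(pts, 0, 5)$V_mV[1], -90)  # -2 nA x 5 MOhm
  expect_equal(correct_voltages(pts, 4.1, 0)$V_mV, pts$V_cmd_mV - 4.1)
  expect_error(correct_voltages(pts, 0, -1), "Rp")
})

test_that("reversal voltage interpolates the bracketing pair nearest 0 mV", {
  cv <- iv_curve(c(-20, 0), c(-10, 10))
  expect_equal(reversal_voltage(cv)$Vr_mV, -10)
  expect_false(reversal_voltage(cv)$extrapolated)
  # exact GHK curve on the 20 mV grid: interpolation error below 0.5 mV
  v <- seq(100, -100, by = -20)
  cv2 <- iv_curve(v, ghk_current(v, 1, 15, 150))
  expect_equal(reversal_voltage(cv2)$Vr_mV, 61.5, tolerance = 0.5)
  # no crossing: extrapolated flag
  cv3 <- iv_curve(c(0, 20, 40), c(10, 30, 50))
  r <- reversal_voltage(cv3)
  expect_true(r$extrapolated)
  expect_equal(r$Vr_mV, -10)
  # interpolated reversal lies between its bracketing voltages
  withr::with_seed(202, {
    for (i in 1:25) {
      I <- sort(rnorm(11, 0, 500))
      if (min(I) >= 0 || max(I) <= 0) next
      cv4 <- iv_curve(v, rev(I))
      r <- reversal_voltage(cv4)
      expect_gte(r$Vr_mV, min(v)); expect_lte(r$Vr_mV, max(v))
    }
  })
})

test_that("terminal conductance is the extreme two-point slope", {
  v <- seq(100, -100, by = -20)
  lin <- iv_curve(v, 10 * v)
  expect_equal(terminal_conductance(lin, "negative"), 10)
  expect_equal(terminal_conductance(lin, "positive"), 10)
  two <- iv_curve(c(-100, -80), c(-2044, -1526))
  expect_equal(terminal_conductance(two, "negative"), 25.9)
  # an inwardly rectifying GHK curve (high external concentration): the
  # terminal slope at the negative extreme exceeds the chord conductance
  # |I(-100)/(-100 - Vr)| — the distinction behind reporting slopes
  cv5 <- iv_curve(v, ghk_current(v, 1, 15, 150))
  vr <- reversal_voltage(cv5)$Vr_mV
  gm <- terminal_conductance(cv5, "negative")
  chord <- abs(current_at(cv5, -100) / (-100 - vr))
  expect_gt(gm, chord)
})

test_that("current_at interpolates and extrapolates on the corrected axis", {
  v <- seq(100, -100, by = -20)
  cv <- iv_curve(v, 10 * v)
  expect_equal(current_at(cv, 100), 1000)
  expect_equal(current_at(cv, -100), -1000)
  # exact point present
  cv2 <- iv_curve(c(-100, -80, 0), c(-1305, -1000, 10))
  expect_equal(current_at(cv2, -100), -1305)
  # extrapolation beyond a contracted span
  cv3 <- iv_curve(c(-92, -72, 0), c(-920, -720, 0))
  expect_equal(current_at(cv3, -100), -1000)
  expect_error(current_at(cv3, -150), "outside")
})

test_that("drug-sensitive difference currents subtract on the control grid", {
  v <- seq(100, -100, by = -20)
  a <- iv_curve(v, 10 * v, condition = "control")
  expect_equal(drug_sensitive_iv(a, a)$I_pA, rep(0, 11))
  # drug = leak-only: the difference is the pure channel current
  ch <- ghk_current(v, 2, 155, 154)
  ctrl <- iv_curve(v, ch + 0.5 * v, condition = "control")
  leak <- iv_curve(v, 0.5 * v, condition = "drug")
  expect_equal(drug_sensitive_iv(ctrl, leak)$I_pA, ch[order(v)])
  far <- iv_curve(c(300, 320), c(1, 2))
  expect_error(drug_sensitive_iv(a, far), "non-overlapping")
})

test_that("percent change reproduces the printed worked numbers", {
  expect_equal(round(percent_inhibition(-2044, -255), 1), 87.5)
  expect_equal(percent_inhibition(-5, -5), 0)
  expect_equal(round(percent_inhibition(-1656, -682), 1), 58.8)
  expect_equal(round(percent_increase(14.1, 16.2), 1), 14.9)
  expect_error(percent_inhibition(0, 1), "reference")
})

test_that("paired transition metrics bracket the bath switch", {
  cell <- cell_default(drift_sd_pA = 0)
  proto <- protocol_spec(preset = NULL, step_duration_ms = 200,
                         repeat_interval_s = 5.3, sample_rate_Hz = 1000)
  B2 <- stock_solution("B2")
  tl <- bath_timeline(list(bath_epoch(0, B2, 0, 2, "a"),
                           bath_epoch(20, B2, 0, 2, "b")), 40)
  b <- simulate_experiment(cell, proto, tl, 0, seed = 5)
  # null transition with rundown off: before equals after
  cell0 <- cell_default(drift_sd_pA = 0,
                        channels = channel_population(rundown_tau = 1e9))
  b0 <- simulate_experiment(cell0, proto, tl, 0, seed = 5)
  tr <- paired_transition_metrics(b0, 20)
  expect_equal(tr$delta_Vr_mV, 0, tolerance = 1e-6)
  expect_equal(tr$after$metrics$I_m100_pA, tr$before$metrics$I_m100_pA,
               tolerance = 1e-6 * abs(tr$before$metrics$I_m100_pA))
  # a transition at t = 0 has no prior sweep
  expect_error(paired_transition_metrics(b, 0), "epoch boundary")
  tl1 <- bath_timeline(list(bath_epoch(0, B2, 0, 2, "a"),
                            bath_epoch(1, B2, 0, 2, "b")), 40)
  b1 <- simulate_experiment(cell, proto, tl1, 0, seed = 5)
  expect_error(paired_transition_metrics(b1, 1), "before the transition")
})

test_that("end-to-end: single-ion reversal equals the Nernst potential
           after full voltage correction", {
  B2 <- stock_solution("B2"); P4 <- stock_solution("P4")
  cell <- cell_default(pipette = P4, drift_sd_pA = 0, leak_nS = 0,
                       channels = channel_population(rundown_tau = 1e9))
  b <- quick_bundle(cell = cell, bath = B2)
  an <- suppressMessages(analyze_bundle(b))
  nernst <- nernst_potential(ion_conc(B2, "Na"), ion_conc(P4, "Na"))
  expect_equal(an$conditions$ctrl$metrics$Vr_mV, nernst, tolerance = 1)
  # the junction offsets applied by the simulator are removed exactly when
  # recomputed from the sidecar solutions
  an_auto <- suppressMessages(analyze_bundle(b, ljp = "auto"))
  expect_equal(an_auto$conditions$ctrl$metrics$Vr_mV,
               an$conditions$ctrl$metrics$Vr_mV, tolerance = 1e-6)
})
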