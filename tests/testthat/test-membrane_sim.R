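# The GHK membrane simulator.

test_that("GHK current: zero at 0 mV for symmetric solutions, continuous
           at the singularity, reverses at the Nernst potential", {
  expect_equal(ghk_current(0, 2, 150, 150), 0)
  lim <- ghk_current(0, 2, 150, 15)
  expect_equal(ghk_current(1e-9, 2, 150, 15), lim, tolerance = 1e-6)
  expect_equal(ghk_current(-1e-9, 2, 150, 15), lim, tolerance = 1e-6)
  # root-finding oracle: the zero crossing of I(V) equals the Nernst value
  withr::with_seed(202, {
    for (i in 1:50) {
      ci <- runif(1, 1, 300); co <- runif(1, 1, 300)
      if (abs(log(co / ci)) < 1e-3) next
      P <- runif(1, 0.1, 10); z <- sample(c(1L, 2L), 1)
      root <- uniroot(function(v) ghk_current(v, P, ci, co, z),
                      c(-300, 300), tol = 1e-12)$root
      expect_equal(root, nernst_potential(co, ci, z), tolerance = 1e-6)
    }
  })
  # single-ion I-V crosses zero at +61.5 mV for 150/15
  root <- uniroot(function(v) ghk_current(v, 1, 15, 150), c(0, 200),
                  tol = 1e-12)$root
  expect_equal(root, 61.5, tolerance = 0.05)
  expect_error(ghk_current(0, -1, 10, 10), "P")
})

test_that("Woodhull block fraction behaves as an open-channel block", {
  expect_equal(block_fraction(-50, 0, 0.4, 0.3), 0)
  kd_at <- function(v) 0.4 * exp(0.3 * v / rt_over_f(310.15))
  expect_equal(block_fraction(-60, kd_at(-60), 0.4, 0.3), 0.5)
  # monotone in B
  b <- seq(0, 5, by = 0.5)
  expect_true(all(diff(block_fraction(-100, b, 0.4, 0.3)) > 0))
  # stronger block at negative potentials for a cationic blocker
  expect_gt(block_fraction(-100, 1, 0.4, 0.3),
            block_fraction(100, 1, 0.4, 0.3))
})

test_that("rundown factor has the exponential half-life identities", {
  expect_equal(rundown_factor(0, 100, 0.3), 1)
  expect_equal(rundown_factor(1e12, 100, 0.3), 0.3)
  expect_equal(rundown_factor(100 * log(2), 100, 0), 0.5)
  expect_error(rundown_factor(1, -5), "tau")
})

test_that("simulator is bit-deterministic and validates its inputs", {
  cell <- cell_default()
  a <- quick_bundle(noise_sd_pA = 20, cell = cell, seed = 42)
  b <- quick_bundle(noise_sd_pA = 20, cell = cell, seed = 42)
  expect_identical(a$current_pA, b$current_pA)
  c <- quick_bundle(noise_sd_pA = 20, cell = cell, seed = 43)
  expect_false(identical(a$current_pA, c$current_pA))
  proto <- protocol_spec(2)
  short <- bath_timeline(list(bath_epoch(0, stock_solution("B2"))), 1)
  expect_error(simulate_experiment(cell, proto, short), "shorter")
})

test_that("noiseless steady state equals the series-resistance fixed-point
           oracle", {
  cell <- cell_default(drift_sd_pA = 0,
                       channels = channel_population(rundown_tau = 1e9))
  b <- quick_bundle(cell = cell)
  an <- suppressMessages(analyze_bundle(b, settle_factor = 0))
  B2 <- stock_solution("B2")
  for (v in c(-100, -60, 20, 100)) {
    ss <- steady_state_current(cell, v, B2)
    got <- an$step_means$I_mean_pA[an$step_means$step_mV == v][1]
    expect_equal(got, ss$I_total_pA, tolerance = 1e-3 * abs(ss$I_total_pA))
  }
})

test_that("NMDG bath leaves only leak plus intracellular Na+ efflux", {
  cell <- cell_default(pipette = stock_solution("P4"), drift_sd_pA = 0,
                       channels = channel_population(rundown_tau = 1e9))
  B5 <- stock_solution("B5")
  ss <- steady_state_current(cell, -100, B5)
  # analytic: leak at Vm plus the GHK efflux term with c_out(Na) = 0
  ch <- cell$channels
  pred <- cell$leak_nS * ss$Vm_mV +
    ghk_current(ss$Vm_mV, ch$P_Na, ion_conc(cell$pipette, "Na"), 0)
  expect_equal(ss$I_total_pA, pred, tolerance = 1e-8)
  expect_gt(ss$I_channel_pA, 0)  # pure efflux is outward even at -100 mV
})

test_that("drug-sensitive current rectifies inwardly at 1 uM block", {
  cell <- cell_default(drift_sd_pA = 0,
                       channels = channel_population(rundown_tau = 1e9))
  B2 <- stock_solution("B2")
  ctrl <- steady_state_current(cell, c(-100, 100), B2, benzamil_uM = 0)
  drug <- steady_state_current(cell, c(-100, 100), B2, benzamil_uM = 1)
  sens <- ctrl$I_total_pA - drug$I_total_pA
  expect_gt(abs(sens[1]), abs(sens[2]))
})

test_that("symmetric K+ currents are small and barely blocker-sensitive", {
  cellK <- cell_default(pipette = stock_solution("P3"), drift_sd_pA = 0,
                        channels = channel_population(rundown_tau = 1e9))
  cellNa <- cell_default(drift_sd_pA = 0,
                         channels = channel_population(rundown_tau = 1e9))
  B3 <- stock_solution("B3"); B2 <- stock_solution("B2")
  iK <- steady_state_current(cellK, -100, B3)$I_total_pA
  iNa <- steady_state_current(cellNa, -100, B2)$I_total_pA
  expect_lt(abs(iK), abs(iNa) / 10)
  iKb <- steady_state_current(cellK, -100, B3, benzamil_uM = 1)$I_total_pA
  expect_lt(abs(percent_inhibition(iK, iKb)), 10)
})

test_that("series cohorts follow their designs", {
  co <- suppressMessages(make_series_cohort(2, n_cells = c(Na = 2, K = 2),
                                            variability = 0, noise_sd_pA = 0,
                                            seed = 9))
  # zero variability: identical cell parameters across the arm
  cells <- lapply(co$arms$Na$bundles, function(b) b$meta$cell)
  expect_equal(cells[[1]]$channels$P_Na, cells[[2]]$channels$P_Na)
  labs <- vapply(co$arms$Na$bundles[[1]]$meta$timeline$epochs, `[[`,
                 character(1), "label")
  expect_true("benzamil" %in% labs)
  co5 <- suppressMessages(make_series_cohort(5, n_cells = 2,
                                             variability = 0,
                                             noise_sd_pA = 0, seed = 9))
  expect_identical(co5$arms$NaNMDG$bundles[[1]]$meta$pipette$label, "P4")
  co4 <- suppressMessages(make_series_cohort(4, n_cells = 2,
                                             variability = 0,
                                             noise_sd_pA = 0, seed = 9))
  tr <- suppressMessages(paired_transition_metrics(co4$arms$NaLi$bundles[[1]],
                                                   co4$design$transition_s))
  expect_lt(tr$before$sweep_time_s, co4$design$transition_s)
  expect_gt(tr$after$sweep_time_s, co4$design$transition_s)
  expect_error(make_series_cohort(7), "series_id")
  expect_error(make_series_cohort(2, n_cells = 1), "n_cells")
})

test_that("trace bundles round-trip through CSV + JSON sidecar", {
  b <- quick_bundle(duration_s = 6, noise_sd_pA = 5,
                    cell = cell_default(drift_sd_pA = 10))
  stem <- tempfile()
  write_trace_bundle(b, stem)
  b2 <- read_trace_bundle(stem)
  expect_equal(b2$current_pA, b$current_pA)
  expect_equal(b2$meta$ljp_by_epoch, b$meta$ljp_by_epoch)
  a1 <- suppressMessages(analyze_bundle(b, settle_factor = 0))
  a2 <- suppressMessages(analyze_bundle(b2, settle_factor = 0))
  expect_equal(a2$conditions$ctrl$metrics$I_m100_pA,
               a1$conditions$ctrl$metrics$I_m100_pA)
  expect_error(read_trace_bundle(tempfile()), "not found")
  # byte-identical CSV payloads for the same seed
  stem2 <- tempfile()
  write_trace_bundle(quick_bundle(duration_s = 6, noise_sd_pA = 5,
                                  cell = cell_default(drift_sd_pA = 10)),
                     stem2)
  expect_identical(readLines(paste0(stem, ".csv")),
                   readLines(paste0(stem2, ".csv")))
})
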