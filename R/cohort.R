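# Experimental-series designs and cohort simulation.
#
# Five canonical series reproduce the study designs the package emulates:
#   1  "physiological"  KCl-rich pipette / NaCl-rich bath, +/- blocker
#   2  "Na or K bath"   symmetric Na+ (P2/B2) and symmetric K+ (P3/B3) arms
#   3  "blocker Na/Li"  Na+ bath +/- blocker, then Li+ bath +/- blocker
#   4  "Na -> Li"       rapid bi-ionic bath switch, no blocker
#   5  "all cations"    15 mM Na+ pipette: Na+ bath +/- blocker, then NMDG+
# Timelines are shortened relative to real bench sessions (a few settled
# sweeps per epoch) but keep the canonical step protocols and repetition
# rates.

.series_designs <- function() {
  p1 <- protocol_spec(1); p2 <- protocol_spec(2)
  list(
    `1` = list(protocol = p1, pipette = "P1", n_default = 7, arms = list(
      phys = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B1"), 0, 2, "control"),
        bath_epoch(67, stock_solution("B1"), benz_uM, 2, "benzamil"),
        bath_epoch(134, stock_solution("B1"), 0, 2, "wash")), 200))),
    `2` = list(protocol = p1, n_default = c(Na = 6, K = 8), arms = list(
      Na = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B2"), 0, 2, "control"),
        bath_epoch(67, stock_solution("B2"), benz_uM, 2, "benzamil"),
        bath_epoch(134, stock_solution("B2"), 0, 2, "wash")), 200),
      K = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B3"), 0, 2, "control"),
        bath_epoch(67, stock_solution("B3"), benz_uM, 2, "benzamil"),
        bath_epoch(134, stock_solution("B3"), 0, 2, "wash")), 200)),
      pipettes = list(Na = "P2", K = "P3")),  # per-arm pipettes
    `3` = list(protocol = p2, pipette = "P2", n_default = 5, arms = list(
      NaLi = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B2"), 0, 2, "Na"),
        bath_epoch(40, stock_solution("B2"), benz_uM, 2, "Na+benz"),
        bath_epoch(80, stock_solution("B2"), 0, 2, "Na.wash"),
        bath_epoch(120, stock_solution("B4"), 0, 2, "Li"),
        bath_epoch(160, stock_solution("B4"), benz_uM, 2, "Li+benz")), 200))),
    `4` = list(protocol = p2, pipette = "P2", n_default = 5, arms = list(
      NaLi = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B2"), 0, 2, "Na"),
        bath_epoch(40, stock_solution("B4"), 0, 2, "Li")), 80)),
      transition_s = 40),
    `5` = list(protocol = p2, pipette = "P4", n_default = 5, arms = list(
      NaNMDG = function(benz_uM) bath_timeline(list(
        bath_epoch(0, stock_solution("B2"), 0, 2, "Na"),
        bath_epoch(40, stock_solution("B2"), benz_uM, 2, "Na+benz"),
        bath_epoch(80, stock_solution("B2"), 0, 2, "Na.wash"),
        bath_epoch(120, stock_solution("B5"), 0, 2, "NMDG")), 160)))
  )
}

#' Canonical series design
#'
#' @param series_id Integer 1-5.
#' @return The design: protocol, pipette label(s), default cohort size and
#'   timeline builders per arm.
#' @export
series_design <- function(series_id) {
  d <- .series_designs()[[as.character(series_id)]]
  if (is.null(d)) stop("unknown series_id: ", series_id)
  d
}

# draw a per-cell parameter variant: log-normal scatter of channel density,
# leak and access resistance around the defaults
.draw_cell <- function(base, variability, pipette) {
  ch <- base$channels
  scale <- function(x) x * exp(stats::rnorm(1, 0, variability))
  rs <- min(max(scale(base$series_resistance_MOhm), 3.3), 9.6)
  cell_model(
    channels = channel_population(P_Na = scale(ch$P_Na),
                                  ratio_Li = ch$ratios[["Li"]],
                                  ratio_K = ch$ratios[["K"]],
                                  ratio_NMDG = ch$ratios[["NMDG"]],
                                  Kd0 = ch$Kd0, delta = ch$delta,
                                  z_blocker = ch$z_blocker,
                                  tau_on = ch$tau_on, tau_off = ch$tau_off,
                                  rundown_tau = ch$rundown_tau,
                                  rundown_floor = ch$rundown_floor),
    pipette = pipette,
    leak_nS = scale(base$leak_nS),
    leak_reversal_mV = base$leak_reversal_mV,
    capacitance_pF = scale(base$capacitance_pF),
    series_resistance_MOhm = rs,
    drift_sd_pA = base$drift_sd_pA, drift_tau_s = base$drift_tau_s,
    temperature_C = base$temperature_C)
}

#' Simulate a cohort of cells for one canonical series
#'
#' Draws per-cell parameters log-normally around the defaults (fractional
#' standard deviation `variability`) and simulates every cell's full
#' recording under the series' timeline.
#'
#' @param series_id Integer 1-5.
#' @param n_cells Cells per arm (>= 2). `NULL` uses the series default.
#' @param variability Fractional (log-normal sigma) cell-to-cell scatter of
#'   channel density, leak, capacitance and access resistance.
#' @param noise_sd_pA White recording noise (pA).
#' @param seed Master seed; all parameter draws and per-cell simulations
#'   derive from it.
#' @param benzamil_uM Blocker concentration in the design's drug epochs.
#' @param base_cell Template [cell_model()] (pipette is replaced per arm).
#' @param ratio_Li Optional override of the Li+/Na+ permeability ratio.
#' @return A `"series_cohort"`: list with `series_id`, `design`, `arms`
#'   (per arm: pipette label and a list of `"trace_bundle"`s) and `seed`.
#' @export
make_series_cohort <- function(series_id, n_cells = NULL, variability = 0.2,
                               noise_sd_pA = 20, seed = 1L, benzamil_uM = 1,
                               base_cell = cell_default(),
                               ratio_Li = NULL) {
  design <- series_design(series_id)
  if (is.null(n_cells)) n_cells <- design$n_default
  if (any(n_cells < 2)) stop("n_cells must be >= 2")
  if (!is.null(ratio_Li)) {
    ch <- base_cell$channels
    base_cell$channels <- channel_population(
      P_Na = ch$P_Na, ratio_Li = ratio_Li, ratio_K = ch$ratios[["K"]],
      ratio_NMDG = ch$ratios[["NMDG"]], Kd0 = ch$Kd0, delta = ch$delta,
      z_blocker = ch$z_blocker, tau_on = ch$tau_on, tau_off = ch$tau_off,
      rundown_tau = ch$rundown_tau, rundown_floor = ch$rundown_floor)
  }
  arm_names <- names(design$arms)
  pipettes <- if (!is.null(design$pipettes)) design$pipettes else
    stats::setNames(rep(list(design$pipette), length(arm_names)), arm_names)
  arms <- list()
  cell_counter <- 0L
  for (arm in arm_names) {
    n_arm <- if (length(n_cells) > 1) n_cells[[arm]] else n_cells
    pip <- stock_solution(pipettes[[arm]])
    timeline <- design$arms[[arm]](benzamil_uM)
    cells <- withr::with_seed(seed + 13L * match(arm, arm_names), {
      lapply(seq_len(n_arm), function(i) .draw_cell(base_cell, variability,
                                                    pip))
    })
    bundles <- lapply(seq_len(n_arm), function(i) {
      cell_counter <<- cell_counter + 1L
      simulate_experiment(cells[[i]], design$protocol, timeline,
                          noise_sd_pA,
                          seed = seed + 7919L * cell_counter)
    })
    arms[[arm]] <- list(pipette = pipettes[[arm]], bundles = bundles)
  }
  structure(list(series_id = series_id, design = design, arms = arms,
                 seed = seed, variability = variability,
                 noise_sd_pA = noise_sd_pA, benzamil_uM = benzamil_uM),
            class = "series_cohort")
}

#' Per-cell, per-condition metrics of a simulated cohort
#'
#' Runs [analyze_bundle()] on every cell and collects one row per cell x
#' settled condition.
#'
#' @param cohort A `"series_cohort"`.
#' @param ... Passed to [analyze_bundle()].
#' @return data.frame with columns `series`, `arm`, `cell`, `condition`,
#'   `Vr_mV`, `I_m100_pA`, `I_p100_pA`, `g_minus_nS`, `g_plus_nS`.
#' @export
cohort_metrics <- function(cohort, ...) {
  rows <- list()
  for (arm in names(cohort$arms)) {
    bundles <- cohort$arms[[arm]]$bundles
    for (i in seq_along(bundles)) {
      an <- analyze_bundle(bundles[[i]], ...)
      for (lab in names(an$conditions)) {
        m <- an$conditions[[lab]]$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          series = cohort$series_id, arm = arm, cell = i, condition = lab,
          Vr_mV = m$Vr_mV, I_m100_pA = m$I_m100_pA, I_p100_pA = m$I_p100_pA,
          g_minus_nS = m$g_minus_nS, g_plus_nS = m$g_plus_nS,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean percent inhibition across a cohort
#'
#' Per cell, 100 (1 - I_drug/I_control) on the chosen metric; then the
#' cohort mean.
#'
#' @param metrics Output of [cohort_metrics()].
#' @param control,drug Condition labels.
#' @param arm Arm name (default: first).
#' @param metric Metric column (default `"I_m100_pA"`).
#' @return List with `per_cell` and `mean_percent`.
#' @export
series_inhibition <- function(metrics, control = "control",
                              drug = "benzamil", arm = NULL,
                              metric = "I_m100_pA") {
  if (is.null(arm)) arm <- metrics$arm[1]
  m <- metrics[metrics$arm == arm, ]
  cells <- sort(unique(m$cell))
  per_cell <- vapply(cells, function(cl) {
    ref <- m[[metric]][m$cell == cl & m$condition == control]
    tst <- m[[metric]][m$cell == cl & m$condition == drug]
    if (length(ref) != 1 || length(tst) != 1) return(NA_real_)
    percent_inhibition(ref, tst)
  }, numeric(1))
  list(per_cell = per_cell, mean_percent = mean(per_cell, na.rm = TRUE))
}

#' Bi-ionic permeability ratio recovered from a Series-4 cohort
#'
#' For each cell, the reversal-voltage shift between the sweeps bracketing
#' the rapid bath switch ([paired_transition_metrics()]) is converted to a
#' permeability ratio with [bionic_permeability_ratio()] using the two
#' baths' major-cation concentrations; the cohort mean shift is also
#' converted directly.
#'
#' @param cohort A Series-4 `"series_cohort"`.
#' @param ... Passed to [paired_transition_metrics()].
#' @return List with `delta_Vr_mV` (per cell), `mean_delta_Vr_mV`,
#'   `ratio_per_cell`, `ratio` (from the mean shift).
#' @export
series4_permeability_ratio <- function(cohort, ...) {
  if (cohort$series_id != 4) stop("expected a Series-4 cohort")
  tr_s <- cohort$design$transition_s
  bundles <- cohort$arms[[1]]$bundles
  T_K <- bundles[[1]]$meta$cell$temperature_C + phys_constants()$zero_celsius
  tl <- bundles[[1]]$meta$timeline
  c_ref <- ion_conc(tl$epochs[[1]]$bath, "Na")
  c_test <- ion_conc(tl$epochs[[2]]$bath, "Li")
  dvr <- vapply(bundles, function(b)
    paired_transition_metrics(b, tr_s, ...)$delta_Vr_mV, numeric(1))
  list(delta_Vr_mV = dvr, mean_delta_Vr_mV = mean(dvr),
       ratio_per_cell = bionic_permeability_ratio(dvr, c_test, c_ref, 1L,
                                                  T_K),
       ratio = bionic_permeability_ratio(mean(dvr), c_test, c_ref, 1L, T_K))
}

#' Null-calibration study of the paired t test
#'
#' Repeatedly simulates small cohorts in which the second bath epoch is a
#' sham exchange (same solution, no blocker, rundown disabled), analyzes
#' them with the standard pipeline, and applies the paired Student t test
#' to the per-cell I(-100) values of the two conditions. Under this null
#' the test should reject at its nominal level.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param n_cells Cells per cohort.
#' @param noise_sd_pA Recording noise.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @param sample_rate_Hz Sampling rate of the (shortened) null protocol.
#' @return List with `reject_rate`, `p_values`.
#' @export
run_null_study <- function(n_seeds = 1000, n_cells = 5, noise_sd_pA = 20,
                           alpha = 0.05, seed = 303L,
                           sample_rate_Hz = 1000) {
  proto <- protocol_spec(preset = NULL, step_duration_ms = 100,
                         repeat_interval_s = 1.2,
                         sample_rate_Hz = sample_rate_Hz)
  bath <- stock_solution("B2")
  timeline <- bath_timeline(list(
    bath_epoch(0, bath, 0, 0.01, "condA"),
    bath_epoch(1.15, bath, 0, 0.01, "condB")), 2.4)
  base <- cell_default(channels = channel_population(rundown_tau = 1e9))
  p_values <- vapply(seq_len(n_seeds), function(k) {
    vals <- vapply(seq_len(n_cells), function(i) {
      cellseed <- seed + 7919L * (k * n_cells + i)
      b <- simulate_experiment(base, proto, timeline, noise_sd_pA,
                               seed = cellseed)
      an <- analyze_bundle(b)
      c(an$conditions$condA$metrics$I_m100_pA,
        an$conditions$condB$metrics$I_m100_pA)
    }, numeric(2))
    stats::t.test(vals[1, ], vals[2, ], paired = TRUE)$p.value
  }, numeric(1))
  list(reject_rate = mean(p_values < alpha), p_values = p_values)
}
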