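# Shared fixtures. Heavy cohort simulations are cached so that several
# tests can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# canonical Series-2 cohort at the package defaults (fixed seed)
series2_cohort <- function() {
  cached("s2", suppressMessages(
    make_series_cohort(2, n_cells = c(Na = 6, K = 8), seed = 101)))
}

series2_metrics <- function() {
  cached("s2m", suppressMessages(cohort_metrics(series2_cohort())))
}

# a small deterministic bundle: symmetric Na+, no noise/drift, 1 kHz
quick_bundle <- function(duration_s = 12, noise_sd_pA = 0,
                         cell = cell_default(drift_sd_pA = 0),
                         bath = stock_solution("B2"), seed = 11) {
  proto <- protocol_spec(preset = NULL, step_duration_ms = 200,
                         repeat_interval_s = 5.3, sample_rate_Hz = 1000)
  tl <- bath_timeline(list(bath_epoch(0, bath, 0, 2, "ctrl")), duration_s)
  simulate_experiment(cell, proto, tl, noise_sd_pA, seed = seed)
}

# random electroneutral solution built from the shipped mobility table
random_solution <- function(label = "rnd") {
  cations <- c("Na", "K", "Li", "NMDG", "Mg", "Ca")
  anions <- c("Cl", "methanesulfonate", "gluconate", "SO4")
  mob <- ion_mobilities()
  ions <- c(stats::setNames(stats::runif(3, 1, 150),
                            sample(cations, 3)),
            stats::setNames(stats::runif(2, 1, 100),
                            sample(anions[-1], 2)))
  z <- mob$z[match(names(ions), mob$name)]
  q <- sum(z * ions)
  if (q > 0) ions["Cl"] <- q else ions["K"] <-
      (if ("K" %in% names(ions)) ions[["K"]] else 0) - q
  make_solution(label, ions, pH = 7.4)
}
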