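#!/usr/bin/env Rscript
# Calibrates the committed default blocker affinity (Kd0) of
# channel_population(): with the electrical distance fixed at delta = 0.3,
# Kd0 is chosen by one-dimensional root-finding so that the full analysis
# pipeline reports 87.5% inhibition of the whole-cell inward current at
# -100 mV by 1 uM blocker, for a single default cell under the symmetric
# Na+ design (deterministic: no noise, no drift, no cell scatter; default
# rundown on, as in a real recording).  The resulting value is committed as
# the channel_population() default.
#
# Run from the repository root:  Rscript scripts/calibrate_defaults.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

pipeline_inhibition <- function(Kd0) {
  cell <- cell_default(
    drift_sd_pA = 0,
    channels = channel_population(Kd0 = Kd0))
  tl <- bath_timeline(list(
    bath_epoch(0, stock_solution("B2"), 0, 2, "control"),
    bath_epoch(67, stock_solution("B2"), 1, 2, "benzamil"),
    bath_epoch(134, stock_solution("B2"), 0, 2, "wash")), 200)
  b <- simulate_experiment(cell, protocol_spec(1), tl, noise_sd_pA = 0,
                           seed = 1)
  an <- suppressMessages(analyze_bundle(b))
  percent_inhibition(an$conditions$control$metrics$I_m100_pA,
                     an$conditions$benzamil$metrics$I_m100_pA)
}

root <- stats::uniroot(function(k) pipeline_inhibition(k) - 87.5,
                       interval = c(0.05, 2), tol = 1e-5)
cat(sprintf("calibrated Kd0 = %.4f uM (pipeline inhibition %.3f%%)\n",
            root$root, pipeline_inhibition(root$root)))
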