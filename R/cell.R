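# Cell model: a GHK-permeability channel population plus blocker, rundown,
# leak, series-resistance, capacitance and noise parameters.

#' Channel population parameters
#'
#' The benzamil-sensitive, Na+-selective conductance. `P_Na` is the
#' effective permeability product for Na+ (pA/mM, see [ghk_current()]);
#' the other cations scale from it by the selectivity ratios. Defaults:
#' P_Li/P_Na = 1.3, P_K/P_Na = 0.002 (a highly selective channel,
#' P_Na/P_K = 500), P_NMDG/P_Na = 0 (impermeant substitute).
#'
#' The blocker model is a Woodhull-type open-channel block
#' ([block_fraction()]); `Kd0` and `delta` are synthetic defaults, not
#' measurements: `delta` is fixed at 0.3 and `Kd0` is calibrated
#' (scripts/calibrate_defaults.R) so that the full analysis pipeline
#' reports 87.5% inhibition of the whole-cell inward current at -100 mV by
#' 1 uM blocker under default noiseless conditions. Bath wash-in/wash-out
#' of the blocker is first-order with `tau_on`/`tau_off`.
#'
#' @param P_Na Effective Na+ permeability product, pA/mM.
#' @param ratio_Li,ratio_K,ratio_NMDG Selectivity ratios P_x/P_Na, >= 0.
#' @param Kd0 Blocker Kd at 0 mV, uM.
#' @param delta Electrical distance of the blocking site, `[0, 1]`.
#' @param z_blocker Blocker valence.
#' @param tau_on,tau_off Blocker exchange time constants, s.
#' @param rundown_tau Rundown time constant, s (`Inf` disables).
#' @param rundown_floor Asymptotic activity fraction, `[0, 1)`.
#' @return An object of class `"channel_population"`.
#' @export
channel_population <- function(P_Na = 3.8, ratio_Li = 1.3, ratio_K = 0.002,
                               ratio_NMDG = 0, Kd0 = 0.3765, delta = 0.3,
                               z_blocker = 1L, tau_on = 2, tau_off = 2,
                               rundown_tau = 1200, rundown_floor = 0.3) {
  stopifnot(P_Na >= 0, ratio_Li >= 0, ratio_K >= 0, ratio_NMDG >= 0,
            Kd0 > 0, delta >= 0, delta <= 1, tau_on > 0, tau_off > 0,
            rundown_tau > 0, rundown_floor >= 0, rundown_floor < 1)
  structure(list(P_Na = P_Na,
                 ratios = c(Na = 1, Li = ratio_Li, K = ratio_K,
                            NMDG = ratio_NMDG),
                 Kd0 = Kd0, delta = delta, z_blocker = z_blocker,
                 tau_on = tau_on, tau_off = tau_off,
                 rundown_tau = rundown_tau, rundown_floor = rundown_floor),
            class = "channel_population")
}

#' Whole-cell model for the voltage-clamp simulator
#'
#' @param channels A [channel_population()].
#' @param pipette Pipette `"solution"` that dialyzes the cytosol
#'   (whole-cell configuration: intracellular composition equals the
#'   pipette recipe).
#' @param leak_nS Ohmic seal/leak conductance, nS, >= 0 (not subject to
#'   rundown or block).
#' @param leak_reversal_mV Leak reversal potential, mV.
#' @param capacitance_pF Whole-cell capacitance, pF, > 0.
#' @param series_resistance_MOhm Pipette access resistance, MOhm, > 0
#'   (typical patch pipettes here: 3.3-9.6 MOhm).
#' @param drift_sd_pA,drift_tau_s Slow baseline instability, modelled as an
#'   Ornstein-Uhlenbeck current offset with stationary standard deviation
#'   `drift_sd_pA` and correlation time `drift_tau_s`. Set `drift_sd_pA = 0`
#'   for a drift-free cell.
#' @param temperature_C Recording temperature.
#' @return An object of class `"cell_model"`.
#' @export
cell_model <- function(channels = channel_population(),
                       pipette = stock_solution("P2"),
                       leak_nS = 0.5, leak_reversal_mV = 0,
                       capacitance_pF = 20, series_resistance_MOhm = 5,
                       drift_sd_pA = 40, drift_tau_s = 30,
                       temperature_C = 37) {
  stopifnot(inherits(channels, "channel_population"),
            inherits(pipette, "solution"),
            leak_nS >= 0, capacitance_pF > 0, series_resistance_MOhm > 0,
            drift_sd_pA >= 0, drift_tau_s > 0)
  structure(list(channels = channels, pipette = pipette, leak_nS = leak_nS,
                 leak_reversal_mV = leak_reversal_mV,
                 capacitance_pF = capacitance_pF,
                 series_resistance_MOhm = series_resistance_MOhm,
                 drift_sd_pA = drift_sd_pA, drift_tau_s = drift_tau_s,
                 temperature_C = temperature_C),
            class = "cell_model")
}

#' Default simulated cell
#'
#' The committed default parameter set ("cell_default"), tuned by
#' scripts/calibrate_defaults.R so that a symmetric Na+-rich recording
#' lands near the whole-cell anchors used throughout the package
#' (I(-100) about -2 nA, terminal slope conductance about 22 nS) and so
#' that 1 uM blocker inhibits the inward current by 87.5%.
#'
#' @param pipette Pipette solution (default P2, Na+-rich).
#' @param ... Overrides passed to [cell_model()].
#' @return A `"cell_model"`.
#' @export
cell_default <- function(pipette = stock_solution("P2"), ...) {
  cell_model(pipette = pipette, ...)
}
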