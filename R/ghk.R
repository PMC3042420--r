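# Core biophysical relations of the simulated membrane: the GHK current
# equation, Woodhull-type voltage-dependent open-channel block, and
# exponential rundown.

#' Goldman-Hodgkin-Katz current through one permeant ion
#'
#' I(V) = P u (c_in - c_out e^{-u}) / (1 - e^{-u}), with u = zFV/RT, the
#' removable singularity at V = 0 handled by its analytic limit
#' I(0) = P (c_in - c_out). `P` is an effective permeability-channel-number
#' product in pA/mM: it folds membrane area, channel density and the usual
#' PF^2/RT factor into one number so that millimolar concentrations yield
#' picoampere currents. Outward current is positive; with a single permeant
#' ion I crosses zero exactly at the Nernst potential.
#'
#' @param V_m Membrane potential in mV (vectorized).
#' @param P Effective permeability product, pA/mM, >= 0.
#' @param c_in,c_out Internal/external concentrations (mM), >= 0.
#' @param z Integer valence.
#' @param temperature_K Absolute temperature (K).
#' @return Current in pA.
#' @export
ghk_current <- function(V_m, P, c_in, c_out, z = 1L,
                        temperature_K = BODY_TEMP_K) {
  if (any(P < 0)) stop("P must be >= 0")
  if (any(c_in < 0) || any(c_out < 0)) stop("concentrations must be >= 0")
  if (any(temperature_K <= 0)) stop("temperature_K must be > 0")
  n <- max(length(V_m), length(c_in), length(c_out))
  u <- rep_len(z * V_m / rt_over_f(temperature_K), n)
  ci <- rep_len(c_in, n)
  co <- rep_len(c_out, n)
  small <- abs(u) < 1e-6
  out <- numeric(n)
  if (any(!small)) {
    us <- u[!small]
    em <- exp(-us)
    out[!small] <- P * us * (ci[!small] - co[!small] * em) / (1 - em)
  }
  if (any(small)) {
    us <- u[small]
    # second-order expansion around u = 0
    out[small] <- P * (ci[small] - co[small] + us * (ci[small] + co[small]) / 2)
  }
  out
}

#' Woodhull-type voltage-dependent block fraction
#'
#' Fraction of channels blocked by a charged open-channel blocker binding at
#' electrical distance `delta` within the field:
#' f = B / (B + Kd0 exp(delta z_b F V / (R T))).
#' For a cationic blocker (z_b = +1) with delta > 0, block is stronger at
#' negative potentials, producing inward rectification of the
#' drug-sensitive current.
#'
#' @param V_m Membrane potential in mV (vectorized).
#' @param B Blocker concentration (uM), >= 0.
#' @param Kd0 Dissociation constant at 0 mV (uM), > 0.
#' @param delta Electrical distance in `[0, 1]`.
#' @param z_blocker Blocker valence (default +1).
#' @param temperature_K Absolute temperature (K).
#' @return Blocked fraction in `[0, 1]`.
#' @export
block_fraction <- function(V_m, B, Kd0, delta, z_blocker = 1L,
                           temperature_K = BODY_TEMP_K) {
  if (any(B < 0)) stop("B must be >= 0")
  if (any(Kd0 <= 0)) stop("Kd0 must be > 0")
  if (any(delta < 0 | delta > 1)) stop("delta must be in [0, 1]")
  kd <- Kd0 * exp(delta * z_blocker * V_m / rt_over_f(temperature_K))
  B / (B + kd)
}

#' Multiplicative rundown factor for channel activity
#'
#' floor + (1 - floor) exp(-t / tau). Applied to channel permeabilities
#' only, never to the leak.
#'
#' @param t Time since whole-cell access, s (vectorized).
#' @param tau Rundown time constant, s, > 0 (`Inf` disables rundown).
#' @param floor Asymptotic fraction in `[0, 1)`.
#' @return Fraction in `(floor, 1]`.
#' @export
rundown_factor <- function(t, tau, floor = 0) {
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(floor < 0 | floor >= 1)) stop("floor must be in [0, 1)")
  floor + (1 - floor) * exp(-t / tau)
}
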