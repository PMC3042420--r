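# I-V curve construction and derived metrics: voltage correction, reversal
# voltage, terminal conductances, currents at +/-100 mV, drug-sensitive
# difference curves and paired bi-ionic transitions.

#' Correct command voltages for junction potential and pipette voltage drop
#'
#' V_corrected = V_cmd - ljp - I Rp, with I in pA and Rp in MOhm
#' (pA x MOhm = uV, hence the 1e-3 factor to mV). Each point is corrected
#' with its own steady-state current.
#'
#' @param points data.frame with columns `V_cmd_mV` and `I_pA`.
#' @param ljp_mV Liquid-junction potential to subtract (mV).
#' @param Rp_MOhm Pipette (series) resistance, >= 0.
#' @return The data.frame with a `V_mV` column added.
#' @export
correct_voltages <- function(points, ljp_mV = 0, Rp_MOhm = 0) {
  if (Rp_MOhm < 0) stop("Rp_MOhm must be >= 0")
  points$V_mV <- points$V_cmd_mV - ljp_mV - points$I_pA * Rp_MOhm * 1e-3
  points
}

#' Build an I-V curve
#'
#' @param V_mV Corrected voltages.
#' @param I_pA Steady-state mean currents.
#' @param I_sd_pA Within-window standard deviations (optional).
#' @param n_samples Samples averaged per point (optional).
#' @param condition Condition label (bath, drug).
#' @param time_s Representative sweep time.
#' @return An `"iv_curve"`: a data.frame sorted by voltage with attributes
#'   `condition` and `time_s`.
#' @export
iv_curve <- function(V_mV, I_pA, I_sd_pA = NA_real_, n_samples = NA_integer_,
                     condition = "", time_s = NA_real_) {
  if (length(V_mV) < 2) stop("an I-V curve needs at least 2 points")
  df <- data.frame(V_mV = V_mV, I_pA = I_pA, I_sd_pA = I_sd_pA,
                   n_samples = n_samples)
  df <- df[order(df$V_mV), ]
  rownames(df) <- NULL
  if (any(diff(df$V_mV) <= 0)) stop("corrected voltages must be distinct")
  structure(df, class = c("iv_curve", "data.frame"),
            condition = condition, time_s = time_s)
}

# linear interpolation with linear extrapolation from the terminal segments
.interp_extrap <- function(x, y, xout) {
  ifelse(xout < x[1],
         y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout - x[1]),
         ifelse(xout > x[length(x)],
                y[length(y)] + (y[length(y)] - y[length(y) - 1]) /
                  (x[length(x)] - x[length(x) - 1]) * (xout - x[length(x)]),
                stats::approx(x, y, xout)$y))
}

#' Reversal voltage of an I-V curve
#'
#' Linear interpolation between the sign-change bracketing pair nearest
#' 0 mV. When the curve does not cross zero, the value is extrapolated
#' from the two points with the smallest |I| and flagged.
#'
#' @param curve An [iv_curve()].
#' @return A list with `Vr_mV` and logical `extrapolated`.
#' @export
reversal_voltage <- function(curve) {
  if (nrow(curve) < 2) stop("curve must have at least 2 points")
  V <- curve$V_mV; I <- curve$I_pA
  cross <- which(I[-length(I)] * I[-1] <= 0 &
                   !(I[-length(I)] == 0 & I[-1] == 0))
  if (length(cross) > 0) {
    # bracketing pair nearest 0 mV
    mid <- (V[cross] + V[cross + 1]) / 2
    k <- cross[which.min(abs(mid))]
    if (I[k] == I[k + 1]) {
      vr <- (V[k] + V[k + 1]) / 2
    } else {
      vr <- V[k] - I[k] * (V[k + 1] - V[k]) / (I[k + 1] - I[k])
    }
    return(list(Vr_mV = vr, extrapolated = FALSE))
  }
  ord <- order(abs(I))[1:2]
  ord <- sort(ord)
  k1 <- ord[1]; k2 <- ord[2]
  slope <- (I[k2] - I[k1]) / (V[k2] - V[k1])
  if (slope == 0) stop("cannot extrapolate a reversal from a flat segment")
  list(Vr_mV = V[k1] - I[k1] / slope, extrapolated = TRUE)
}

#' Terminal slope conductance
#'
#' Slope dI/dV between the two most extreme corrected points of the
#' requested polarity, in nS (pA/mV). This is a local slope, not the chord
#' I/(V - Vr); for rectifying currents the two differ and the slope is the
#' quantity reported here.
#'
#' @param curve An [iv_curve()].
#' @param polarity `"negative"` (g-) or `"positive"` (g+).
#' @return Conductance in nS.
#' @export
terminal_conductance <- function(curve,
                                 polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  V <- curve$V_mV; I <- curve$I_pA
  if (polarity == "negative") {
    side <- order(V)[1:2]
  } else {
    side <- order(V, decreasing = TRUE)[1:2]
  }
  if (length(V) < 2) stop("need at least 2 points on the requested side")
  diff(I[side]) / diff(V[side])
}

#' Current at a target corrected voltage
#'
#' Linear interpolation on the corrected curve, with linear extrapolation
#' from the terminal segment when the corrected span falls short of the
#' target by at most `tol_mV` (series-resistance correction contracts the
#' span, so +/-100 mV usually lies slightly outside it).
#'
#' @param curve An [iv_curve()].
#' @param V_mV Target voltage (typically +100 or -100).
#' @param tol_mV Maximum allowed extrapolation distance (default 10 mV).
#' @return Current in pA.
#' @export
current_at <- function(curve, V_mV, tol_mV = 10) {
  V <- curve$V_mV
  if (V_mV < min(V) - tol_mV || V_mV > max(V) + tol_mV)
    stop(sprintf("target %g mV outside corrected span [%g, %g] +/- %g",
                 V_mV, min(V), max(V), tol_mV))
  .interp_extrap(V, curve$I_pA, V_mV)
}

#' Drug-sensitive difference current
#'
#' Pointwise control minus drug on the control curve's corrected voltage
#' grid; the drug curve is re-interpolated onto the control voltages.
#'
#' @param control,drug [iv_curve()]s with overlapping voltage ranges.
#' @return An `"iv_curve"` of the difference current.
#' @export
drug_sensitive_iv <- function(control, drug) {
  if (min(drug$V_mV) > max(control$V_mV) ||
      max(drug$V_mV) < min(control$V_mV))
    stop("control and drug curves have non-overlapping voltage ranges")
  I_drug <- .interp_extrap(drug$V_mV, drug$I_pA, control$V_mV)
  iv_curve(control$V_mV, control$I_pA - I_drug,
           condition = paste0(attr(control, "condition"), " - ",
                              attr(drug, "condition")),
           time_s = attr(control, "time_s"))
}

#' Percent inhibition / percent increase
#'
#' `percent_inhibition` returns 100 (1 - test/reference) — the phrasing for
#' a drug reducing a current; `percent_increase` returns
#' 100 (test/reference - 1) — the phrasing for, e.g., a conductance rising
#' after an ion substitution.
#'
#' @param reference,test Values in the same units; `reference` nonzero.
#' @return Percent change.
#' @examples
#' percent_inhibition(-2044, -255)  # 87.5
#' percent_increase(14.1, 16.2)     # 14.9
#' @export
percent_inhibition <- function(reference, test) {
  if (any(reference == 0)) stop("reference must be nonzero")
  100 * (1 - test / reference)
}

#' @rdname percent_inhibition
#' @export
percent_increase <- function(reference, test) {
  if (any(reference == 0)) stop("reference must be nonzero")
  100 * (test / reference - 1)
}

#' Full metric set of an I-V curve
#'
#' @param curve An [iv_curve()].
#' @param tol_mV Extrapolation allowance passed to [current_at()]. The
#'   default (40 mV) covers the worst-case contraction of the corrected
#'   span by the series-resistance voltage drop (about 4 nA x 9.6 MOhm).
#' @return An `"iv_metrics"` list: `Vr_mV`, `Vr_extrapolated`, `I_m100_pA`,
#'   `I_p100_pA`, `g_minus_nS`, `g_plus_nS`.
#' @export
iv_metrics <- function(curve, tol_mV = 40) {
  vr <- reversal_voltage(curve)
  structure(list(Vr_mV = vr$Vr_mV, Vr_extrapolated = vr$extrapolated,
                 I_m100_pA = current_at(curve, -100, tol_mV),
                 I_p100_pA = current_at(curve, 100, tol_mV),
                 g_minus_nS = terminal_conductance(curve, "negative"),
                 g_plus_nS = terminal_conductance(curve, "positive")),
            class = "iv_metrics")
}
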