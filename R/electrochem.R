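# Equilibrium electrochemistry: Nernst potentials, bi-ionic GHK permeability
# ratios, Henderson liquid-junction potentials, Ca-EGTA buffering, ideal
# osmolarity.

#' Nernst equilibrium potential
#'
#' E = (RT/zF) ln(c_out/c_in), in mV. Antisymmetric under swapping the two
#' concentrations and scaling as 1/z.
#'
#' @param c_out,c_in Concentrations (mM), both > 0.
#' @param z Integer valence, nonzero.
#' @param temperature_K Absolute temperature (default 310.15 K, i.e. 37 C).
#' @return Potential in mV.
#' @examples
#' nernst_potential(150, 15)   # ~ +61.5 mV for a monovalent cation at 37 C
#' @export
nernst_potential <- function(c_out, c_in, z = 1L,
                             temperature_K = BODY_TEMP_K) {
  if (any(c_out <= 0)) stop("c_out must be > 0")
  if (any(c_in <= 0)) stop("c_in must be > 0")
  if (any(z == 0)) stop("z must be nonzero")
  if (any(temperature_K <= 0)) stop("temperature_K must be > 0")
  rt_over_f(temperature_K) / z * log(c_out / c_in)
}

#' Bi-ionic permeability ratio from a reversal-voltage shift
#'
#' For sequential substitution of the external permeant cation (reference
#' ion, concentration `c_out_ref`, replaced by a test ion at `c_out_test`),
#' the GHK voltage equation gives a reversal-voltage shift
#' dVr = (RT/zF) ln(P_test c_test / (P_ref c_ref)). This function inverts
#' that relation:
#' P_test/P_ref = (c_out_ref/c_out_test) exp(z F dVr / (R T)).
#'
#' @param delta_Vr Reversal-voltage shift in mV (test minus reference).
#' @param c_out_test,c_out_ref External concentrations (mM), > 0.
#' @param z Integer valence of the permeant ions.
#' @param temperature_K Absolute temperature (K).
#' @return Dimensionless permeability ratio P_test/P_ref.
#' @examples
#' bionic_permeability_ratio(7.0, 150, 150)  # ~1.3 for Li+ vs Na+ at 37 C
#' @export
bionic_permeability_ratio <- function(delta_Vr, c_out_test, c_out_ref,
                                      z = 1L, temperature_K = BODY_TEMP_K) {
  if (any(c_out_test <= 0)) stop("c_out_test must be > 0")
  if (any(c_out_ref <= 0)) stop("c_out_ref must be > 0")
  if (any(temperature_K <= 0)) stop("temperature_K must be > 0")
  (c_out_ref / c_out_test) *
    exp(z * delta_Vr / rt_over_f(temperature_K))
}

#' Predicted reversal-voltage shift for a bi-ionic substitution
#'
#' Forward form of [bionic_permeability_ratio()]; useful for simulation
#' design and round-trip checks.
#'
#' @param ratio P_test/P_ref, > 0.
#' @inheritParams bionic_permeability_ratio
#' @return Shift in mV.
#' @export
bionic_delta_vr <- function(ratio, c_out_test, c_out_ref, z = 1L,
                            temperature_K = BODY_TEMP_K) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  rt_over_f(temperature_K) / z * log(ratio * c_out_test / c_out_ref)
}

#' Henderson liquid-junction potential
#'
#' Computes the Henderson-equation junction potential between a pipette and
#' a bath solution, using limiting equivalent conductivities as relative
#' mobilities. The returned value is the potential of the bath relative to
#' the pipette — the sign convention in which the value is subtracted from
#' the command potential to obtain the true membrane potential. The
#' simulator and the analyzer share this convention.
#'
#' @param pipette,bath `"solution"` objects (see [make_solution()],
#'   [stock_solution()]).
#' @param mobilities Mobility table; see [ion_mobilities()] and
#'   [read_mobility_table()].
#' @param temperature_K Absolute temperature (K).
#' @return Junction potential in mV (bath minus pipette).
#' @examples
#' henderson_ljp(stock_solution("P3"), stock_solution("B2"))
#' @export
henderson_ljp <- function(pipette, bath, mobilities = ion_mobilities(),
                          temperature_K = BODY_TEMP_K) {
  species <- union(names(pipette$ions), names(bath$ions))
  idx <- match(species, mobilities$name)
  if (anyNA(idx))
    stop("no mobility entry for species: ",
         paste(species[is.na(idx)], collapse = ", "))
  lam <- mobilities$lambda0[idx]
  z <- mobilities$z[idx]
  cA <- ion_conc(pipette, species)   # A = pipette
  cB <- ion_conc(bath, species)      # B = bath
  if (max(abs(cA - cB)) < 1e-12) return(0)
  rt <- rt_over_f(temperature_K)
  dc <- cB - cA
  num <- sum(sign(z) * lam * dc)
  den <- sum(abs(z) * lam * dc)
  SA <- sum(abs(z) * lam * cA)
  SB <- sum(abs(z) * lam * cB)
  if (abs(den) < 1e-9 * max(SA, SB)) {
    # denominator of the Henderson prefactor vanishes: evaluate the
    # underlying linear-mixing integral numerically instead
    f <- function(x) {
      sapply(x, function(xx) {
        cx <- cA + xx * dc
        sum(sign(z) * lam * dc) / sum(abs(z) * lam * cx)
      })
    }
    return(-rt * stats::integrate(f, 0, 1)$value)
  }
  rt * (num / den) * log(SA / SB)
}

#' Free calcium in a 1:1 Ca-EGTA buffer
#'
#' Solves the single-site binding equilibrium
#' Ca_total = Ca_free + EGTA_total Ca_free / (Kd + Ca_free) for Ca_free
#' (the root of a quadratic, taken in `[0, total_Ca]`). The default apparent
#' Kd (172.5 nM) is calibrated so that the canonical Na-rich pipette recipe
#' (0.367 mM Ca, 1 mM EGTA, pH 7.3, 37 C) is buffered to 100 nM free Ca2+.
#'
#' @param total_Ca,total_EGTA Total concentrations in mM, >= 0.
#' @param Kd_app Apparent dissociation constant in nM, > 0.
#' @return Free Ca2+ concentration in nM.
#' @examples
#' free_calcium(0.367, 1.0)  # ~100 nM
#' @export
free_calcium <- function(total_Ca, total_EGTA, Kd_app = 172.5) {
  if (any(total_Ca < 0)) stop("total_Ca must be >= 0")
  if (any(total_EGTA < 0)) stop("total_EGTA must be >= 0")
  if (any(Kd_app <= 0)) stop("Kd_app must be > 0")
  kd_mM <- Kd_app * 1e-6
  b <- total_EGTA + kd_mM - total_Ca
  free_mM <- (-b + sqrt(b^2 + 4 * kd_mM * total_Ca)) / 2
  free_mM * 1e6
}

#' Ideal osmolarity of a solution
#'
#' Sum of all dissociated ion and neutral solute concentrations with unit
#' osmotic coefficients. This is an upper-bound sanity check on recipes, not
#' a measurement model (measured osmolarities run slightly lower).
#'
#' @param sol A `"solution"` object.
#' @return Osmolarity in mOsm.
#' @export
ideal_osmolarity <- function(sol) {
  sum(sol$ions) + sum(sol$neutrals)
}
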