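# Solution objects: named ionic inventories with pH and temperature.
#
# Recipes are entered as salts; the constructor dissociates them into a full
# ionic inventory, splits HEPES into its neutral and anionic forms by
# Henderson-Hasselbalch (pKa 7.5), treats EGTA as the doubly deprotonated
# 2- species at these pH values, and adds the pH titrant cation (NaOH, KOH,
# LiOH or NMDG base, as named in the recipe) by electroneutrality.

HEPES_PKA <- 7.5

#' Construct a solution from an ionic inventory
#'
#' @param label Identifier (e.g. `"B2"` or a user label).
#' @param ions Named numeric vector of fully dissociated ion concentrations
#'   in mM. Names must have valence entries in `mobilities`.
#' @param neutrals Named numeric vector of neutral solute concentrations
#'   in mM (glucose, neutral HEPES fraction, ...).
#' @param pH Solution pH.
#' @param temperature_C Temperature in degrees Celsius (default 37).
#' @param mobilities Mobility/valence table, see [ion_mobilities()].
#' @return An object of class `"solution"`.
#' @export
make_solution <- function(label, ions, neutrals = numeric(0), pH = 7.4,
                          temperature_C = 37, mobilities = ion_mobilities()) {
  ions <- unlist(ions); neutrals <- unlist(neutrals)
  if (is.null(names(ions)) || any(!nzchar(names(ions))))
    stop("ions must be a named vector (mM)")
  if (any(ions < 0)) stop("ion concentrations must be >= 0")
  if (length(neutrals) && any(neutrals < 0))
    stop("neutral solute concentrations must be >= 0")
  z <- .ion_valence(names(ions), mobilities)
  imbalance <- sum(z * ions)
  if (abs(imbalance) > 5)
    stop(sprintf("solution '%s': net charge imbalance %.2f mM equiv exceeds 5",
                 label, imbalance))
  structure(list(label = label, ions = ions, neutrals = neutrals, pH = pH,
                 temperature_C = temperature_C),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf("<solution %s>  pH %.1f, %.0f C\n", x$label, x$pH,
              x$temperature_C))
  cat("  ions (mM):",
      paste(sprintf("%s=%.3g", names(x$ions), x$ions), collapse = ", "), "\n")
  if (length(x$neutrals))
    cat("  neutral (mM):",
        paste(sprintf("%s=%.3g", names(x$neutrals), x$neutrals),
              collapse = ", "), "\n")
  invisible(x)
}

#' Net ionic charge imbalance of a solution
#'
#' @param sol A [make_solution()] object.
#' @return Signed imbalance in mM equivalents (positive = excess cations).
#' @export
charge_imbalance <- function(sol) {
  z <- .ion_valence(names(sol$ions))
  sum(z * sol$ions)
}

# recipe table for the canonical bath (B1-B5) and pipette (P1-P4) solutions:
# salts in mM, with the pH titrant base named in the recipe
.solution_recipes <- function() {
  list(
    B1 = list(salts = c(NaCl = 150, KCl = 4, MgCl2 = 1, CaCl2 = 0.7),
              glucose = 5, HEPES = 10, EGTA = 0, pH = 7.4, titrant = "Na"),
    B2 = list(salts = c(Na_ms = 150, Ca_gluconate = 0.7, MgSO4 = 1),
              glucose = 5, HEPES = 10, EGTA = 0, pH = 7.4, titrant = "Na"),
    B3 = list(salts = c(K_ms = 150, Ca_gluconate = 0.7, MgSO4 = 1),
              glucose = 5, HEPES = 10, EGTA = 0, pH = 7.4, titrant = "K"),
    B4 = list(salts = c(Li_ms = 150, Ca_gluconate = 0.7, MgSO4 = 1),
              glucose = 5, HEPES = 10, EGTA = 0, pH = 7.4, titrant = "Li"),
    B5 = list(salts = c(NMDG_ms = 150, Ca_gluconate = 0.7, MgSO4 = 1),
              glucose = 5, HEPES = 10, EGTA = 0, pH = 7.4, titrant = "NMDG"),
    P1 = list(salts = c(NaCl = 10, KCl = 140, MgCl2 = 1, CaCl2 = 0.273),
              glucose = 0, HEPES = 10, EGTA = 1, pH = 7.2, titrant = "K"),
    P2 = list(salts = c(Na_ms = 150, Ca_gluconate = 0.367, MgSO4 = 1),
              glucose = 0, HEPES = 10, EGTA = 1, pH = 7.3, titrant = "Na"),
    P3 = list(salts = c(K_ms = 150, Ca_gluconate = 0.367, MgSO4 = 1),
              glucose = 0, HEPES = 10, EGTA = 1, pH = 7.3, titrant = "K"),
    P4 = list(salts = c(Na_ms = 15, NMDG_ms = 135, Ca_gluconate = 0.367,
                        MgSO4 = 1),
              glucose = 0, HEPES = 10, EGTA = 1, pH = 7.3, titrant = "NMDG")
  )
}

# salt -> ions dissociation map: list of c(ion = stoichiometry)
.salt_ions <- list(
  NaCl = c(Na = 1, Cl = 1), KCl = c(K = 1, Cl = 1),
  MgCl2 = c(Mg = 1, Cl = 2), CaCl2 = c(Ca = 1, Cl = 2),
  Na_ms = c(Na = 1, methanesulfonate = 1),
  K_ms = c(K = 1, methanesulfonate = 1),
  Li_ms = c(Li = 1, methanesulfonate = 1),
  NMDG_ms = c(NMDG = 1, methanesulfonate = 1),
  Ca_gluconate = c(Ca = 1, gluconate = 2),
  MgSO4 = c(Mg = 1, SO4 = 1)
)

#' Labels of the canonical solutions
#' @return Character vector `c("B1".."B5", "P1".."P4")`.
#' @export
solution_labels <- function() names(.solution_recipes())

#' Build a canonical bath or pipette solution
#'
#' Dissociates the recipe salts, splits HEPES into neutral and anionic forms
#' at the recipe pH (pKa 7.5), carries EGTA as the 2- species, and adds the
#' recipe's titrant cation to electroneutrality.
#'
#' @param label One of [solution_labels()].
#' @return A `"solution"` object.
#' @examples
#' stock_solution("B2")
#' @export
stock_solution <- function(label) {
  rec <- .solution_recipes()[[label]]
  if (is.null(rec)) stop("unknown solution label: ", label)
  ions <- numeric(0)
  for (s in names(rec$salts)) {
    st <- .salt_ions[[s]]
    for (ion in names(st)) {
      ions[ion] <- (if (ion %in% names(ions)) ions[ion] else 0) +
        st[[ion]] * rec$salts[[s]]
    }
  }
  frac_anion <- 1 / (1 + 10^(HEPES_PKA - rec$pH))
  if (rec$HEPES > 0) ions["HEPES"] <- rec$HEPES * frac_anion
  if (rec$EGTA > 0) ions["EGTA"] <- rec$EGTA
  z <- .ion_valence(names(ions))
  deficit <- -sum(z * ions)        # anion excess to be matched by titrant
  if (deficit < 0)
    stop("recipe ", label, " has excess cations before titration")
  ions[rec$titrant] <- (if (rec$titrant %in% names(ions)) ions[rec$titrant]
                        else 0) + deficit
  neutrals <- c(glucose = rec$glucose,
                HEPES0 = rec$HEPES * (1 - frac_anion))
  neutrals <- neutrals[neutrals > 0]
  make_solution(label, ions, neutrals, pH = rec$pH, temperature_C = 37)
}

#' Concentration of one ion in a solution
#' @param sol A `"solution"`.
#' @param name Ion species name.
#' @return Concentration in mM (0 when absent).
#' @export
ion_conc <- function(sol, name) {
  out <- sol$ions[name]
  out[is.na(out)] <- 0
  unname(out)
}

#' Write / read a solution as JSON
#'
#' The document mirrors the recipe-table row structure: label, ionic
#' inventory (mM), neutral solutes, pH and temperature.
#'
#' @param sol A `"solution"` object.
#' @param path File path.
#' @return `read_solution_json` returns a `"solution"`; `write_solution_json`
#'   returns `path` invisibly.
#' @export
write_solution_json <- function(sol, path) {
  jsonlite::write_json(list(label = sol$label, ions = as.list(sol$ions),
                            neutrals = as.list(sol$neutrals), pH = sol$pH,
                            temperature_C = sol$temperature_C),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution_json
#' @export
read_solution_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_solution(x$label, unlist(x$ions), unlist(x$neutrals), x$pH,
                x$temperature_C)
}
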