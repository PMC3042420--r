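# Ion species and limiting equivalent conductivities.
#
# The shipped table collects published limiting equivalent conductivities
# (lambda0, S cm^2 equiv^-1 at 25 C; CRC Handbook values for the inorganic
# ions, patch-clamp junction-potential literature for the organic ones).
# lambda0 is used only for Henderson liquid-junction potentials, where a
# proportionality constant common to all species cancels.  The EGTA entry is
# an estimate for the doubly deprotonated species (documented; its
# millimolar-level contribution to any junction here is negligible).

.ghk_env <- new.env(parent = emptyenv())

#' Read a mobility table from a CSV file
#'
#' The file must have columns `name`, `z` (integer valence, nonzero) and
#' `lambda0` (limiting equivalent conductivity, S cm^2 equiv^-1, > 0).
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `name`, `z`, `lambda0`.
#' @export
read_mobility_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "z", "lambda0")
  if (!all(need %in% names(tab)))
    stop("mobility table must have columns name, z, lambda0")
  if (any(tab$z == 0)) stop("mobility table: valence z must be nonzero")
  if (any(tab$lambda0 <= 0)) stop("mobility table: lambda0 must be > 0")
  if (anyDuplicated(tab$name)) stop("mobility table: duplicated species name")
  tab[need]
}

#' Default limiting-equivalent-conductivity table
#'
#' Published 25 C limiting equivalent conductivities for the ions occurring
#' in standard patch-clamp bath and pipette solutions (Na+, K+, Li+, NMDG+,
#' Cl-, methanesulfonate-, gluconate-, SO4^2-, Mg2+, Ca2+, HEPES-, ...).
#' The table ships as `extdata/limiting_conductivities.csv` and can be
#' replaced with [read_mobility_table()].
#'
#' @return A data.frame with columns `name`, `z`, `lambda0`.
#' @export
ion_mobilities <- function() {
  if (is.null(.ghk_env$mobilities)) {
    path <- system.file("extdata", "limiting_conductivities.csv",
                        package = "ghkclamp")
    .ghk_env$mobilities <- read_mobility_table(path)
  }
  .ghk_env$mobilities
}

# valence lookup for the species the package knows about; solutions may add
# others as long as the mobility table covers them
.ion_valence <- function(name, mobilities = ion_mobilities()) {
  idx <- match(name, mobilities$name)
  if (anyNA(idx)) {
    stop("unknown ion species (no valence/mobility entry): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  mobilities$z[idx]
}
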