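# Physical constants and element data (atomic units internally).

#' Physical constants used by shieldens
#'
#' All internal quantities are in Hartree atomic units: lengths in bohr,
#' current-density susceptibilities in a.u., shielding tensors dimensionless
#' (reported as ppm, i.e. multiplied by 1e6). In atomic units the SI
#' Biot-Savart prefactor mu0/4pi becomes alpha^2, the square of the
#' fine-structure constant.
#'
#' @format A named list with elements `fine_structure` (alpha, CODATA 2018),
#'   `alpha2` (alpha^2, the Biot-Savart prefactor in a.u.),
#'   `bohr_per_angstrom` (conversion factor), `ppm` (1e6).
#' @export
shieldens_constants <- list(
  fine_structure    = 0.0072973525693,
  alpha2            = 0.0072973525693^2,
  bohr_per_angstrom = 1.8897261254578281,
  ppm               = 1e6
)

# element symbol -> nuclear charge (H..Kr is ample for organic ring systems)
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36
)

# Bragg-Slater radii in angstrom (Slater 1964), used as the size parameters
# of the Becke cell functions.  Becke's recommendation of 0.35 A for hydrogen
# (instead of Slater's 0.25 A) is applied when `hydrogen_becke = TRUE`.
.bragg_slater_A <- c(
  H = 0.25, He = 1.20, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70, N = 0.65,
  O = 0.60, F = 0.50, Ne = 1.50, Na = 1.80, Mg = 1.50, Al = 1.25, Si = 1.10,
  P = 1.00, S = 1.00, Cl = 1.00, Ar = 1.80, K = 2.20, Ca = 1.80, Sc = 1.60,
  Ti = 1.40, V = 1.35, Cr = 1.40, Mn = 1.40, Fe = 1.40, Co = 1.35, Ni = 1.35,
  Cu = 1.35, Zn = 1.35, Ga = 1.30, Ge = 1.25, As = 1.15, Se = 1.15, Br = 1.15,
  Kr = 1.90
)

#' Becke cell radius of an element
#'
#' Returns the Bragg-Slater radius (bohr) used in the Becke cell functions.
#' With `hydrogen_becke = TRUE` (the default used throughout the package)
#' hydrogen is assigned 0.35 angstrom as recommended by Becke.
#'
#' @param element Character vector of element symbols.
#' @param hydrogen_becke Use 0.35 angstrom for H instead of 0.25.
#' @return Numeric vector of radii in bohr.
#' @export
element_radius <- function(element, hydrogen_becke = TRUE) {
  r <- .bragg_slater_A[element]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  if (hydrogen_becke) r[element == "H"] <- 0.35
  unname(r) * shieldens_constants$bohr_per_angstrom
}

#' Nuclear charge of an element
#'
#' @param element Character vector of element symbols (H..Kr).
#' @return Integer vector of nuclear charges.
#' @export
element_charge <- function(element) {
  z <- .element_z[element]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(as.integer(z))
}

# default Gaussian exponent ranges per element for radial grid construction,
# bracketing triple-zeta quality basis sets (steepest s exponent, most
# diffuse valence exponent).  Used when no basis is available.
.radial_alpha_defaults <- list(
  H  = c(0.10, 34.1),
  He = c(0.16, 98.1),
  Li = c(0.02, 6269.0),
  Be = c(0.04, 14630.0),
  B  = c(0.06, 23870.0),
  C  = c(0.10, 13575.0),
  N  = c(0.13, 19730.0),
  O  = c(0.17, 27032.0),
  F  = c(0.22, 35479.0),
  Ne = c(0.28, 45069.0)
)

`%||%` <- function(a, b) if (is.null(a)) b else a
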