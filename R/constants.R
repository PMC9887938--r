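#' Physical constants and unit conversion helpers
#'
#' Internal unit conventions: optical-trap quantities are carried in
#' pN, nm and s (so trap stiffness is pN/nm, drag is pN s/nm, power spectra
#' are nm^2/Hz); traction force microscopy quantities in Pa and um.
#' These helpers are the single place where conversions between the two
#' conventions (and to SI) live.
#'
#' @name units
NULL

#' Boltzmann constant in pN nm / K.
#'
#' 1.380649e-23 J/K expressed in the trap unit convention
#' (1 J = 1e21 pN nm).
#' @export
KB_PN_NM <- 1.380649e-23 * 1e21

#' Thermal energy k_B T in pN nm
#'
#' @param temperature_K absolute temperature in kelvin
#' @return k_B T in pN nm (about 4.116 pN nm at 298.15 K)
#' @export
kbt_pN_nm <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  KB_PN_NM * temperature_K
}

#' Stokes drag coefficient of a sphere, in pN s / nm
#'
#' gamma = 6 pi eta r for a sphere of radius `radius_um` in a fluid of
#' viscosity `viscosity_Pa_s`. In SI, Pa s m = N s / m; the conversion to
#' pN s / nm is a factor 1e3 per (Pa s um).
#'
#' @param radius_um bead radius in micrometres
#' @param viscosity_Pa_s dynamic viscosity in Pa s
#' @return drag coefficient in pN s / nm
#' @examples
#' stokes_drag_pN_s_nm(1.08, 1e-3) # ~2.036e-5 pN s/nm
#' @export
stokes_drag_pN_s_nm <- function(radius_um, viscosity_Pa_s) {
  stopifnot(radius_um > 0, viscosity_Pa_s > 0)
  6 * pi * viscosity_Pa_s * radius_um * 1e-3
}

#' Convert an integrated traction (Pa um^2) to nanonewtons
#'
#' 1 Pa um^2 = 1e-12 N = 1e-3 nN.
#'
#' @param x force in Pa um^2
#' @return force in nN
#' @export
pa_um2_to_nN <- function(x) x * 1e-3

#' Convert strain energy in Pa um^3 to femtojoules
#'
#' 1 Pa um^3 = 1e-18 J = 1e-3 fJ.
#'
#' @param x energy in Pa um^3
#' @return energy in fJ
#' @export
pa_um3_to_fJ <- function(x) x * 1e-3

#' Young's modulus from shear modulus
#'
#' E = 2 G' (1 + nu) for an isotropic linear-elastic solid.
#'
#' @param shear_modulus_Pa shear modulus G' in Pa
#' @param poisson_ratio Poisson's ratio nu
#' @return Young's modulus in Pa
#' @export
young_from_shear <- function(shear_modulus_Pa, poisson_ratio) {
  2 * shear_modulus_Pa * (1 + poisson_ratio)
}

# run `expr` under a temporary RNG seed without disturbing the caller's
# RNG stream; all package randomness goes through here
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Derive reproducible per-stage sub-seeds from a master seed
#'
#' A documented counter scheme: sub-seed i is
#' (seed * 1000003 + i) mod (2^31 - 1), kept in the positive 32-bit integer
#' range. Used by the pipeline so each stage gets an independent,
#' reproducible stream.
#'
#' @param seed master seed (integer)
#' @param i stage counter (integer >= 1), possibly vectorized
#' @return integer sub-seed(s)
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i)) %% (2^31 - 1))
}
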