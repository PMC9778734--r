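#' Physical constants used throughout the package
#'
#' All energies are in kcal·mol⁻¹, distances in Å, times in ps and
#' temperatures in K. `kB` is the Boltzmann (gas) constant in
#' kcal·mol⁻¹·K⁻¹; `planck_h` is Planck's constant in kcal·mol⁻¹·s
#' (per mole), so that `kB * T / planck_h` is the Eyring prefactor in s⁻¹.
#'
#' @format Named numeric constants.
#' @name constants
NULL

#' @rdname constants
#' @export
kB <- 0.0019872041

# Planck constant expressed per mole in kcal·mol^-1·s:
# 6.62607015e-34 J·s * 6.02214076e23 mol^-1 / 4184 J·kcal^-1
#' @rdname constants
#' @export
planck_h <- 6.62607015e-34 * 6.02214076e23 / 4184

#' @rdname constants
#' @export
default_temperature <- 310

.beta <- function(temperature) 1 / (kB * temperature)
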