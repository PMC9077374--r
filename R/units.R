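# Internal unit system: lengths in nm, times in ps.
# User-facing chemistry stays in the field's customary units
# (rate constants in M^-1 s^-1, diffusion coefficients in cm^2 s^-1).

AVOGADRO <- 6.02214076e23

# 1 M^-1 s^-1 = 1e24 nm^3 / (N_A * 1e12 ps) per molecule pair
K_M1S1_TO_NM3PS <- 1e12 / AVOGADRO

# 1 cm^2 s^-1 = 1e14 nm^2 / 1e12 ps
D_CM2S_TO_NM2PS <- 100

# 1 s^-1 = 1e-12 ps^-1
RATE_S_TO_PS <- 1e-12

# Molarity of liquid water at 25 C, used to fold the bimolecular
# electron + water reaction into a pseudo-first-order channel.
WATER_MOLARITY <- 55.34

#' Unit conversions between laboratory and simulation units
#'
#' The simulation works internally in nanometres and picoseconds.
#' `k_bimolecular_nm3ps()` converts a bimolecular rate constant from
#' \eqn{M^{-1} s^{-1}} to the per-pair reaction volume rate
#' \eqn{nm^3\,ps^{-1}} (division by Avogadro's number plus the
#' litre-to-nm\eqn{^3} and second-to-ps factors); `diffusion_nm2ps()`
#' converts a diffusion coefficient from \eqn{cm^2 s^{-1}} to
#' \eqn{nm^2\,ps^{-1}}.
#'
#' @param k_M1s1 bimolecular rate constant(s) in \eqn{M^{-1} s^{-1}}.
#' @param D_cm2s diffusion coefficient(s) in \eqn{cm^2 s^{-1}}.
#' @return Numeric vector in simulation units.
#' @examples
#' k_bimolecular_nm3ps(2.5e10)  # ~0.0415 nm^3/ps
#' diffusion_nm2ps(4.9e-5)     # 4.9e-3 nm^2/ps
#' @export
k_bimolecular_nm3ps <- function(k_M1s1) k_M1s1 * K_M1S1_TO_NM3PS

#' @rdname k_bimolecular_nm3ps
#' @export
diffusion_nm2ps <- function(D_cm2s) D_cm2s * D_CM2S_TO_NM2PS

# complementary error function and its inverse via the normal quantile
erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))
erfcinv_ <- function(y) -stats::qnorm(y / 2) / sqrt(2)
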