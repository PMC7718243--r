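#' Physical constants and unit conversions
#'
#' Helpers shared by the signal models. Frequency offsets are expressed in
#' ppm of the proton resonance frequency; saturation amplitudes B1 in µT.
#'
#' @name units
NULL

#' Proton gyromagnetic ratio (rad s^-1 T^-1)
#' @export
GAMMA_1H <- 2.675e8

#' Default proton resonance frequency at 7 T, in MHz
#' @export
DEFAULT_F0_MHZ <- 300.06

#' Convert a chemical-shift offset from ppm to angular frequency
#'
#' @param ppm offset in ppm
#' @param f0_mhz proton resonance frequency in MHz
#' @return offset in rad/s
#' @export
ppm_to_radsec <- function(ppm, f0_mhz = DEFAULT_F0_MHZ) {
  2 * pi * ppm * f0_mhz
}

#' Convert a ppm offset to Hz
#' @inheritParams ppm_to_radsec
#' @return offset in Hz
#' @export
ppm_to_hz <- function(ppm, f0_mhz = DEFAULT_F0_MHZ) {
  ppm * f0_mhz
}

#' Saturation amplitude B1 (µT) to nutation frequency omega1 (rad/s)
#'
#' omega1 = gamma * B1 for protons.
#'
#' @param b1_ut B1 in µT
#' @return omega1 in rad/s
#' @export
b1_to_omega1 <- function(b1_ut) {
  GAMMA_1H * b1_ut * 1e-6
}
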