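#' Analytic field of a 2D line current in free space
#'
#' Outgoing cylindrical wave of an infinite z-directed line current `I` under
#' the exp(+j omega t) convention:
#' `E_z(r) = -(omega * mu0 * I / 4) * H0^(2)(k0 r)`, with `H0^(2)` the
#' zeroth-order Hankel function of the second kind. This is the closed-form
#' oracle used to validate the 2D solver in free space.
#'
#' @param r Radial distance from the source in metres (> 0), vectorized.
#' @param frequency Frequency in Hz.
#' @param amplitude Complex line-current amplitude in A.
#' @return Complex `E_z` in V/m.
#' @export
analytic_line_source <- function(r, frequency, amplitude = 1) {
  if (any(r <= 0)) stop("`r` must be > 0")
  k <- physical_constants()
  w <- 2 * pi * frequency
  k0 <- w / k$c
  h02 <- besselJ(k0 * r, 0) - 1i * besselY(k0 * r, 0)
  -(w * k$mu0 * amplitude / 4) * h02
}

#' Line-current amplitude radiating a given power
#'
#' A 2D line current `I` radiates `P' = omega * mu0 * |I|^2 / 8` watts per
#' metre in free space; this returns the amplitude whose per-metre radiated
#' power equals `power` (the feed-point calibration used so that a 2D array
#' element is comparable to a dipole transmitting at the same power).
#'
#' @param power Radiated power in W (per metre of line).
#' @param frequency Frequency in Hz.
#' @return Real amplitude in A.
#' @export
source_amplitude_for_power <- function(power, frequency) {
  k <- physical_constants()
  sqrt(8 * power / (2 * pi * frequency * k$mu0))
}
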