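#' Design a half-wave-style dipole from centre frequency and resonance factor
#'
#' Applies the standard design chain for a centre-fed cylindrical dipole:
#' wavelength `lambda = c / f_c` (with the engineering value `c = 3e8` m/s, the
#' convention under which a 1 GHz, `R_f = 0.46` design gives exactly
#' `L = 138 mm`), antenna length `L = R_f * lambda`, arm length `L_a = L / 2`,
#' wire radius `L_a / 20` and feed gap `L_a / 100`.
#'
#' @param f_c Centre frequency in Hz (> 0).
#' @param R_f Resonance (shortening) factor in (0, 1); 0.46 gives resonance
#'   slightly below the half-wave length for a thick dipole.
#' @param Z0 Reference impedance for S11 (ohms).
#' @param drive_impedance Source impedance the element is driven from (ohms).
#' @param V0 Drive voltage (V).
#' @param power Transmit power in W.
#' @param c_design Speed of light used by the design chain (m/s).
#' @return An object of class `antenna_design` with all derived dimensions in
#'   mm.
#' @export
#' @examples
#' design_dipole(1e9)
design_dipole <- function(f_c, R_f = 0.46, Z0 = 78, drive_impedance = 75,
                          V0 = 1, power = 6.6e-3, c_design = 3e8) {
  if (f_c <= 0) stop("`f_c` must be > 0")
  if (R_f <= 0 || R_f >= 1) stop("`R_f` must be in (0, 1)")
  if (power <= 0) stop("`power` must be > 0")
  wavelength <- c_design / f_c
  length_mm <- R_f * wavelength * 1000
  arm_mm <- length_mm / 2
  structure(
    list(f_c = f_c, wavelength = wavelength, R_f = R_f,
         length_mm = length_mm, arm_mm = arm_mm,
         radius_mm = arm_mm / 20, gap_mm = arm_mm / 100,
         Z0 = Z0, drive_impedance = drive_impedance, V0 = V0, power = power),
    class = "antenna_design"
  )
}

#' @export
print.antenna_design <- function(x, ...) {
  cat("<antenna_design> f_c = ", signif(x$f_c / 1e9, 4), " GHz, L = ",
      signif(x$length_mm, 6), " mm (R_f = ", x$R_f, "), radius = ",
      signif(x$radius_mm, 6), " mm, gap = ", signif(x$gap_mm, 6), " mm\n",
      sep = "")
  invisible(x)
}

#' Tabulate an antenna design
#'
#' @param x An `antenna_design`.
#' @param ... Unused.
#' @return One-row tibble of the design parameters.
#' @export
tidy.antenna_design <- function(x, ...) {
  tibble::tibble(
    f_c = x$f_c, wavelength_m = x$wavelength, R_f = x$R_f,
    length_mm = x$length_mm, arm_mm = x$arm_mm, radius_mm = x$radius_mm,
    gap_mm = x$gap_mm, Z0 = x$Z0, drive_impedance = x$drive_impedance,
    V0 = x$V0, power_W = x$power
  )
}

#' Feed-point impedance of a cylindrical dipole (induced-EMF method)
#'
#' Classical induced-EMF input impedance of a centre-fed cylindrical dipole of
#' length `L` and wire radius `a`, assuming a sinusoidal current distribution;
#' the maximum-current-referred resistance and reactance are referred to the
#' feed through `sin^2(kL/2)`. In the thin half-wave limit this reduces to the
#' textbook 73 + 42.5j ohms. Valid for `0.1 <= L/lambda <= 0.9`.
#'
#' @param design An [design_dipole()] result.
#' @param f Frequency in Hz; defaults to the design centre frequency.
#' @return Complex input impedance in ohms (vectorized over `f`).
#' @export
input_impedance <- function(design, f = design$f_c) {
  stopifnot(inherits(design, "antenna_design"))
  k <- physical_constants()
  L <- design$length_mm / 1000
  a <- design$radius_mm / 1000
  Llam <- L * f / k$c
  if (any(Llam < 0.1 | Llam > 0.9)) {
    stop("L/lambda outside the sinusoidal-current validity band [0.1, 0.9]")
  }
  eta <- sqrt(k$mu0 / k$eps0)
  gamma <- 0.57721566490153286
  kl <- 2 * pi * f / k$c * L
  Si <- pracma::Si; Ci <- pracma::Ci
  Rm <- eta / (2 * pi) * (
    gamma + log(kl) - Ci(kl) +
      0.5 * sin(kl) * (Si(2 * kl) - 2 * Si(kl)) +
      0.5 * cos(kl) * (gamma + log(kl / 2) + Ci(2 * kl) - 2 * Ci(kl))
  )
  Xm <- eta / (4 * pi) * (
    2 * Si(kl) + cos(kl) * (2 * Si(kl) - Si(2 * kl)) -
      sin(kl) * (2 * Ci(kl) - Ci(2 * kl) - Ci(2 * kl * a^2 / L^2))
  )
  complex(real = Rm, imaginary = Xm) / sin(kl / 2)^2
}

#' Reflection coefficient in dB
#'
#' `S11 = 20 log10 |(Z_in - Z0) / (Z_in + Z0)|`; always <= 0, with a perfect
#' match clipped at `floor_db`.
#'
#' @param z_in Complex input impedance (ohms), vectorized.
#' @param Z0 Real reference impedance (> 0).
#' @param floor_db Clipping floor for a perfect match.
#' @return S11 in dB.
#' @export
s11 <- function(z_in, Z0, floor_db = -100) {
  if (Z0 <= 0) stop("`Z0` must be > 0")
  gam <- Mod((z_in - Z0) / (z_in + Z0))
  out <- ifelse(gam == 0, floor_db, 20 * log10(gam))
  pmax(out, floor_db)
}

#' Place an elliptical multi-static antenna array around the head
#'
#' Positions `n` elements at equal parametric angles on an ellipse whose
#' semi-axes are the head's in-plane semi-axes plus the standoff. Element 1
#' sits on the +x side and numbering runs counter-clockwise, so with `n = 8`
#' element 7 faces -y (the nose under this package's coordinate convention).
#'
#' @param semi_axes In-plane head semi-axes (a, b) in mm.
#' @param n Number of elements (>= 3).
#' @param standoff Radial standoff in mm (> 0); values outside the customary
#'   30-40 mm band raise a warning.
#' @param z Plane coordinate attached to every element (mm).
#' @return A tibble (`element`, `x`, `y`, `z`) with attributes `standoff` and
#'   `semi_axes`.
#' @export
#' @examples
#' place_array(c(90, 110), n = 8, standoff = 35)
place_array <- function(semi_axes, n = 8, standoff = 35, z = 0) {
  if (standoff <= 0) stop("`standoff` must be > 0")
  if (n < 3) stop("`n` must be >= 3")
  if (standoff < 30 || standoff > 40) {
    warning("standoff outside the customary 30-40 mm band")
  }
  t <- (seq_len(n) - 1) * 2 * pi / n
  out <- tibble::tibble(
    element = seq_len(n),
    x = (semi_axes[1] + standoff) * cos(t),
    y = (semi_axes[2] + standoff) * sin(t),
    z = z
  )
  attr(out, "standoff") <- standoff
  attr(out, "semi_axes") <- semi_axes
  out
}

#' Multi-static acquisition schedule
#'
#' One entry per transmission: element k transmits, the other n - 1 receive;
#' the total receiver-channel count is n (n - 1).
#'
#' @param n Number of elements (>= 2).
#' @return A tibble with columns `tx` and list-column `rx`.
#' @export
multistatic_schedule <- function(n) {
  if (n < 2) stop("`n` must be >= 2 for a multi-static schedule")
  tibble::tibble(
    tx = seq_len(n),
    rx = lapply(seq_len(n), function(k) setdiff(seq_len(n), k))
  )
}
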