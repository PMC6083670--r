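#' Perfectly-matched-layer specification
#'
#' Stretched-coordinate PML with polynomial conductivity grading
#' `sigma_pml(d) = sigma_max * (d / L)^order`, where `d` is the depth into the
#' layer and `L` its total thickness. `sigma_max` is chosen so that the
#' theoretical normal-incidence round-trip reflection from the backing wall
#' equals `target_reflection`.
#'
#' @param thickness Layer thickness in cells (>= 4).
#' @param order Polynomial grading order.
#' @param target_reflection Design normal-incidence amplitude reflection.
#' @return An object of class `pml_spec`.
#' @export
pml_spec <- function(thickness = 12, order = 3, target_reflection = 1e-6) {
  if (thickness < 4) stop("PML thickness must be at least 4 cells")
  structure(list(thickness = as.integer(thickness), order = order,
                 target_reflection = target_reflection),
            class = "pml_spec")
}

#' Per-axis complex stretch profiles for a PML
#'
#' Builds, for each axis of a grid, the complex coordinate-stretch function
#' `s(x) = 1 - 1i * sigma_pml(x) / (omega * eps0)`; the stretch is exactly 1 in
#' the interior.
#'
#' @param node_coords List of node coordinate vectors (mm), one per axis.
#' @param pml A [pml_spec()] (or thickness in cells).
#' @param frequency Frequency in Hz.
#' @param order,target_reflection Used when `pml` is a bare thickness.
#' @return List of per-axis profile objects, each with elements `s` (function
#'   of position in mm, vectorized), `sigma_max` (S/m), `depth_mm`, and the
#'   interior interval `interior` (mm).
#' @export
make_pml <- function(node_coords, pml = pml_spec(), frequency,
                     order = 3, target_reflection = 1e-6) {
  if (!inherits(pml, "pml_spec")) {
    pml <- pml_spec(thickness = pml, order = order,
                    target_reflection = target_reflection)
  }
  k <- physical_constants()
  w <- 2 * pi * frequency
  lapply(node_coords, function(xs) {
    n_cells <- length(xs) - 1L
    if (n_cells < 2L * pml$thickness + 2L) {
      stop("grid too small for a ", pml$thickness, "-cell PML on both sides")
    }
    h <- xs[2] - xs[1]
    L_mm <- pml$thickness * h
    L_m <- L_mm / 1000
    sigma_max <- -(pml$order + 1) * k$eps0 * k$c *
      log(pml$target_reflection) / (2 * L_m)
    lo <- min(xs) + L_mm
    hi <- max(xs) - L_mm
    s_fun <- function(x) {
      d <- pmax(0, lo - x) + pmax(0, x - hi)      # depth into either layer, mm
      sig <- sigma_max * pmin(d / L_mm, 1)^pml$order
      1 - 1i * sig / (w * k$eps0)
    }
    list(s = s_fun, sigma_max = sigma_max, depth_mm = L_mm,
         interior = c(lo, hi), order = pml$order,
         target_reflection = pml$target_reflection)
  })
}
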