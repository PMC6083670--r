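#' Physical constants used throughout the package
#'
#' Vacuum permittivity, permeability and speed of light in SI units. The
#' consistency `c = 1/sqrt(mu0 * eps0)` holds to machine precision.
#'
#' @return A named list with elements `eps0` (F/m), `mu0` (H/m) and `c` (m/s).
#' @export
#' @examples
#' k <- physical_constants()
#' k$c * sqrt(k$mu0 * k$eps0)  # 1
physical_constants <- function() {
  mu0 <- 4e-7 * pi
  c0 <- 299792458
  list(eps0 = 1 / (mu0 * c0^2), mu0 = mu0, c = c0)
}

#' Canonical head-tissue vocabulary
#'
#' The 21 canonical tissue classes used after tissue mapping, with their
#' integer labels and the relaxation model each class is evaluated with
#' (fourth-order Debye for 17 classes, fourth-order Cole-Cole for 4), plus the
#' two stroke labels used by [insert_stroke()].
#'
#' @return A tibble with columns `canonical_id`, `tissue`, `model_tag`.
#' @export
canonical_tissues <- function() {
  tibble::tibble(
    canonical_id = 1:21,
    tissue = c(
      "air/free space", "skin (dry)", "skin (wet)", "fat", "bone, cortical",
      "bone, cancellous", "white matter (WM)", "grey matter (GM)", "blood",
      "cerebrospinal fluid (CSF)", "dura", "bone marrow", "cerebellum",
      "spinal cord (nerve)", "eye tissue (sclera)", "cartilage",
      "muscle, parallel", "stomach", "tongue", "trachea", "eye lens (nucleus)"
    ),
    model_tag = c(rep("debye4", 17), rep("colecole4", 4))
  )
}

# integer labels used by the synthetic phantom and the stroke inserter
TISSUE_ID <- c(
  air = 1L, skin = 2L, fat = 4L, bone = 5L, wm = 7L, gm = 8L,
  csf = 10L, dura = 11L
)
STROKE_ID <- c(haemorrhagic = 22L, ischaemic = 23L)

#' Default dielectric override values for stroke tissue at 1 GHz
#'
#' Bleeding (haemorrhagic) tissue is assigned `eps_r = 61.0650`,
#' `sigma = 1.5829` S/m; ischaemic tissue `eps_r = 30`, `sigma = 0.5` S/m.
#' These are fixed 1 GHz constants; a dispersive stroke model can be supplied
#' through the `override` field of [stroke_spec()].
#'
#' @param kind `"haemorrhagic"` or `"ischaemic"`.
#' @return Named numeric vector `c(eps_r, sigma)`.
#' @export
stroke_defaults <- function(kind = c("haemorrhagic", "ischaemic")) {
  kind <- match.arg(kind)
  switch(kind,
    haemorrhagic = c(eps_r = 61.0650, sigma = 1.5829),
    ischaemic = c(eps_r = 30, sigma = 0.5)
  )
}
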