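#' Fourth-order relaxation model parameters for one tissue
#'
#' Container for the coefficients of a fourth-order Cole-Cole or Debye
#' dispersion model: complex relative permittivity
#' \deqn{\tilde\varepsilon_r(\omega) = \varepsilon_\infty +
#'   \sum_{m=1}^{4} \frac{\Delta\varepsilon_m}{1 + (j\omega\tau_m)^{1-\alpha_m}}
#'   + \frac{\sigma_s}{j\omega\varepsilon_0}}
#' under the exp(+j omega t) time convention. The Debye model is the
#' alpha = 0 special case.
#'
#' @param model_tag `"debye4"` or `"colecole4"`.
#' @param eps_inf Optical-limit permittivity, >= 1.
#' @param deps Four pole amplitudes (dimensionless).
#' @param tau Four relaxation times (seconds, > 0).
#' @param alpha Four broadening exponents in `[0, 1)`; must be all zero for
#'   `"debye4"`.
#' @param sigma_static Static conductivity (S/m, >= 0).
#' @return An object of class `dispersion_params`.
#' @export
dispersion_params <- function(model_tag = c("debye4", "colecole4"),
                              eps_inf, deps, tau, alpha = rep(0, 4),
                              sigma_static = 0) {
  model_tag <- match.arg(model_tag)
  if (length(deps) != 4L || length(tau) != 4L || length(alpha) != 4L) {
    stop("exactly 4 poles are required (deps, tau, alpha of length 4)")
  }
  if (eps_inf < 1) stop("`eps_inf` must be >= 1")
  if (any(tau <= 0)) stop("relaxation times `tau` must be > 0")
  if (any(alpha < 0 | alpha >= 1)) stop("`alpha` must lie in [0, 1)")
  if (model_tag == "debye4" && any(alpha != 0)) {
    stop("debye4 requires all alpha = 0")
  }
  if (sigma_static < 0) stop("`sigma_static` must be >= 0")
  structure(list(model_tag = model_tag, eps_inf = eps_inf,
                 deps = as.numeric(deps), tau = as.numeric(tau),
                 alpha = as.numeric(alpha),
                 sigma_static = as.numeric(sigma_static)),
            class = "dispersion_params")
}

#' Evaluate a dispersion model at given frequencies
#'
#' Returns the complex relative permittivity
#' `eps_r(omega) - 1i * sigma(omega)/(omega * eps0)`. The principal branch is
#' used for `(j omega tau)^(1-alpha)`, which guarantees passivity
#' (`sigma(omega) >= 0`) for non-negative pole amplitudes.
#'
#' @param params A [dispersion_params()].
#' @param frequency Frequencies in Hz (> 0); vectorized.
#' @return Complex vector, one value per frequency.
#' @export
#' @examples
#' wm <- head_dispersion_params()[["white matter (WM)"]]
#' split_complex(eval_dispersion(wm, 1e9), 1e9)
eval_dispersion <- function(params, frequency) {
  stopifnot(inherits(params, "dispersion_params"))
  if (any(frequency <= 0)) stop("`frequency` must be > 0")
  k <- physical_constants()
  w <- 2 * pi * frequency
  out <- rep(params$eps_inf + 0i, length(w))
  for (m in 1:4) {
    out <- out + params$deps[m] /
      (1 + (1i * w * params$tau[m])^(1 - params$alpha[m]))
  }
  out + params$sigma_static / (1i * w * k$eps0)
}

#' Split a complex relative permittivity into (eps_r, sigma)
#'
#' Under the exp(+j omega t) convention, `eps_r = Re(eps)` and
#' `sigma = -omega * eps0 * Im(eps)`; this is the algebraic inverse of
#' [complex_permittivity()].
#'
#' @param eps Complex relative permittivity (vectorized).
#' @param frequency Frequency in Hz (> 0).
#' @return A list with numeric elements `eps_r` and `sigma` (S/m).
#' @export
split_complex <- function(eps, frequency) {
  if (any(frequency <= 0)) stop("`frequency` must be > 0")
  k <- physical_constants()
  list(eps_r = Re(eps), sigma = -2 * pi * frequency * k$eps0 * Im(eps))
}

#' Compose a complex relative permittivity from (eps_r, sigma)
#'
#' @param eps_r Relative permittivity (dimensionless).
#' @param sigma Conductivity (S/m).
#' @param frequency Frequency in Hz (> 0).
#' @return Complex `eps_r - 1i * sigma / (omega * eps0)`.
#' @export
complex_permittivity <- function(eps_r, sigma, frequency) {
  if (any(frequency <= 0)) stop("`frequency` must be > 0")
  k <- physical_constants()
  eps_r - 1i * sigma / (2 * pi * frequency * k$eps0)
}

#' Load dispersion parameter sets for the canonical head tissues
#'
#' Reads a dispersion parameter CSV (columns `tissue`, `model_tag`, `eps_inf`,
#' `deps1..deps4`, `tau1..tau4`, `alpha1..alpha4`, `sigma_static`). The default
#' is the synthetic parameter file shipped with the package, whose evaluation
#' at 1 GHz reproduces the published per-tissue (eps_r, sigma) table.
#'
#' @param path CSV file path.
#' @return Named list of [dispersion_params()], keyed by tissue name.
#' @export
head_dispersion_params <- function(path = system.file(
                                     "extdata", "head_dispersion_synthetic.csv",
                                     package = "mwihead")) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("tissue", "model_tag", "eps_inf", paste0("deps", 1:4),
            paste0("tau", 1:4), paste0("alpha", 1:4), "sigma_static")
  if (!all(need %in% names(tb))) {
    stop("dispersion file must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tb)), function(r) {
    dispersion_params(
      model_tag = tb$model_tag[r],
      eps_inf = tb$eps_inf[r],
      deps = as.numeric(tb[r, paste0("deps", 1:4)]),
      tau = as.numeric(tb[r, paste0("tau", 1:4)]),
      alpha = as.numeric(tb[r, paste0("alpha", 1:4)]),
      sigma_static = tb$sigma_static[r]
    )
  })
  stats::setNames(out, tb$tissue)
}

# validity band (Hz) within which a model's parameterization is trusted
model_validity_band <- function(model_tag) {
  switch(model_tag,
    debye4 = c(1e8, 3e9),        # head-tissue Debye fit band
    colecole4 = c(10, 2e10),
    c(0, Inf)
  )
}

#' Tabulate (eps_r, sigma) for tissues across frequencies
#'
#' Evaluates each tissue's dispersion model at each frequency. Duplicate
#' frequencies are deduplicated with stable order; frequencies outside a
#' model's validity band raise a warning, not an error.
#'
#' @param tissue_params Named list of [dispersion_params()], e.g. from
#'   [head_dispersion_params()].
#' @param frequencies Frequencies in Hz (non-empty, > 0).
#' @return A tibble with columns `tissue`, `frequency`, `eps_r`, `sigma`.
#' @export
frequency_sweep <- function(tissue_params, frequencies) {
  if (length(frequencies) == 0L) stop("`frequencies` must be non-empty")
  frequencies <- frequencies[!duplicated(frequencies)]
  if (any(frequencies <= 0)) stop("`frequency` must be > 0")
  rows <- purrr::imap(tissue_params, function(p, nm) {
    band <- model_validity_band(p$model_tag)
    if (any(frequencies < band[1] | frequencies > band[2])) {
      warning("frequencies outside the ", p$model_tag,
              " validity band for tissue '", nm, "'", call. = FALSE)
    }
    sp <- split_complex(eval_dispersion(p, frequencies), frequencies)
    tibble::tibble(tissue = nm, frequency = frequencies,
                   eps_r = sp$eps_r, sigma = sp$sigma)
  })
  dplyr::bind_rows(rows)
}

#' Build a per-cell dielectric map from a phantom
#'
#' Assigns each voxel (3D phantom) or cell (2D slice) the (eps_r, sigma) of its
#' tissue label evaluated at `frequency`; the map is piecewise constant. A
#' [stroke_spec()] either relabels geometrically (voxels within the sphere and
#' not air receive the override values) or, for phantoms already carrying
#' stroke labels from [insert_stroke()], the labels are mapped through the
#' stroke override directly. `kind = "none"` yields the healthy map.
#'
#' @param phantom A [voxel_phantom()] or `phantom_slice`.
#' @param tissue_params Named list of [dispersion_params()] keyed by tissue
#'   name (see [head_dispersion_params()]); every canonical label present must
#'   have an entry.
#' @param frequency Frequency in Hz.
#' @param stroke Optional [stroke_spec()].
#' @return An object of class `dielectric_map`: arrays `eps_r` and `sigma`
#'   congruent with the label grid, plus `frequency`, `spacing`, `origin`.
#' @export
build_dielectric_map <- function(phantom, tissue_params = head_dispersion_params(),
                                 frequency = 1e9, stroke = NULL) {
  is_slice <- inherits(phantom, "phantom_slice")
  labels <- phantom$labels
  ct <- canonical_tissues()
  id2name <- stats::setNames(ct$tissue, ct$canonical_id)

  present <- sort(unique(as.integer(labels)))
  lut_eps <- rep(NA_real_, max(present))
  lut_sig <- rep(NA_real_, max(present))
  for (id in present) {
    if (id %in% STROKE_ID) {
      kind <- names(STROKE_ID)[match(id, STROKE_ID)]
      ov <- if (!is.null(stroke) && !is.null(stroke$override) &&
                stroke$kind == kind) stroke$override else stroke_defaults(kind)
      lut_eps[id] <- ov[[1]]; lut_sig[id] <- ov[[2]]
      next
    }
    nm <- id2name[as.character(id)]
    if (is.na(nm) || is.null(tissue_params[[nm]])) {
      stop("no dispersion parameters for tissue label ", id,
           if (!is.na(nm)) paste0(" ('", nm, "')"))
    }
    sp <- split_complex(eval_dispersion(tissue_params[[nm]], frequency),
                        frequency)
    lut_eps[id] <- sp$eps_r; lut_sig[id] <- sp$sigma
  }
  eps_r <- array(lut_eps[as.integer(labels)], dim = dim(labels))
  sigma <- array(lut_sig[as.integer(labels)], dim = dim(labels))

  if (!is.null(stroke) && stroke$kind != "none" &&
      !any(as.integer(labels) %in% STROKE_ID)) {
    ov <- if (!is.null(stroke$override)) stroke$override else
      stroke_defaults(stroke$kind)
    if (is_slice) {
      co <- slice_coords(phantom)
      centre2 <- stroke$centre[match(phantom$axes, c("x", "y", "z"))]
      dfix <- stroke$centre[match(phantom$fixed_axis, c("x", "y", "z"))] -
        phantom$fixed_coord
      r2 <- stroke$radius^2 - dfix^2
      if (r2 > 0) {
        d2 <- outer((co[[1]] - centre2[1])^2, (co[[2]] - centre2[2])^2, "+")
        hit <- d2 <= r2 & labels != TISSUE_ID[["air"]]
      } else hit <- array(FALSE, dim(labels))
    } else {
      hit <- voxel_dist2(phantom, stroke$centre) <= stroke$radius^2 &
        labels != TISSUE_ID[["air"]]
    }
    if (!any(hit)) stop("stroke outside head: sphere contains no tissue voxel")
    eps_r[hit] <- ov[[1]]; sigma[hit] <- ov[[2]]
  }

  structure(
    list(eps_r = eps_r, sigma = sigma, frequency = frequency,
         spacing = phantom$spacing, origin = phantom$origin,
         labels = labels,
         axes = if (is_slice) phantom$axes else c("x", "y", "z")),
    class = "dielectric_map"
  )
}

#' @export
print.dielectric_map <- function(x, ...) {
  cat("<dielectric_map> ", paste(dim(x$eps_r), collapse = " x "),
      " cells at ", signif(x$frequency / 1e9, 4), " GHz; eps_r in [",
      signif(min(x$eps_r), 4), ", ", signif(max(x$eps_r), 4),
      "], sigma in [", signif(min(x$sigma), 4), ", ",
      signif(max(x$sigma), 4), "] S/m\n", sep = "")
  invisible(x)
}

#' Complex permittivity array of a dielectric map
#'
#' @param map A `dielectric_map`.
#' @return Complex array `eps_r - 1i * sigma/(omega * eps0)`.
#' @export
map_complex_eps <- function(map) {
  complex_permittivity(map$eps_r, map$sigma, map$frequency)
}

#' Tidy a dielectric map into a long tibble
#'
#' @param x A `dielectric_map` (2D).
#' @param ... Unused.
#' @return Tibble with cell-centre coordinates, `eps_r` and `sigma`.
#' @export
tidy.dielectric_map <- function(x, ...) {
  d <- dim(x$eps_r)
  if (length(d) != 2L) stop("tidy() supports 2D dielectric maps")
  co <- list(axis_coords(d[1], x$spacing[1], x$origin[1]),
             axis_coords(d[2], x$spacing[2], x$origin[2]))
  out <- tibble::tibble(
    a = rep(co[[1]], times = d[2]),
    b = rep(co[[2]], each = d[1]),
    eps_r = as.numeric(x$eps_r),
    sigma = as.numeric(x$sigma)
  )
  names(out)[1:2] <- x$axes
  out
}

#' Plot a 2D dielectric map
#'
#' @param object A `dielectric_map`.
#' @param what `"eps_r"` or `"sigma"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dielectric_map <- function(object, what = c("eps_r", "sigma"), ...) {
  what <- match.arg(what)
  df <- tidy.dielectric_map(object)
  nms <- names(df)
  ggplot2::ggplot(df, ggplot2::aes(.data[[nms[1]]], .data[[nms[2]]],
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(nms[1], "(mm)"), y = paste(nms[2], "(mm)")) +
    ggplot2::theme_minimal()
}
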