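#' Specific absorption rate map from a solved field
#'
#' `SAR = sigma |E|^2 / (2 rho)` per cell (W/kg) for peak-phasor fields; with
#' `field_convention = "rms"` the factor 2 is dropped. |E| is averaged from
#' the four surrounding nodes onto each cell centre so it is congruent with
#' the conductivity map. Air cells are excluded (reported as `NA`).
#'
#' @param field A `field_solution` (2D).
#' @param rho Tissue mass density (kg/m^3), scalar or cell-grid matrix;
#'   default the uniform 1050 kg/m^3 head average.
#' @param field_convention `"peak"` (default, includes the factor 2) or
#'   `"rms"`.
#' @return An object of class `sar_map`: the SAR matrix on the cell grid plus
#'   labels, spacing and cell-centre coordinates.
#' @export
sar_map <- function(field, rho = 1050, field_convention = c("peak", "rms")) {
  stopifnot(inherits(field, "field_solution"))
  field_convention <- match.arg(field_convention)
  map <- field$dielectric
  d <- dim(map$sigma)
  if (length(d) != 2L) stop("sar_map() supports 2D fields")
  en <- Mod(field$E)
  e_cell <- (en[-1, -1] + en[-(d[1] + 1L), -1] +
               en[-1, -(d[2] + 1L)] + en[-(d[1] + 1L), -(d[2] + 1L)]) / 4
  tissue <- map$labels != TISSUE_ID[["air"]]
  if (is.matrix(rho)) {
    if (!identical(dim(rho), d)) stop("`rho` matrix must match the cell grid")
    if (any(rho[tissue] <= 0)) stop("`rho` must be > 0 wherever evaluated")
    rho_eval <- rho
  } else {
    if (rho <= 0) stop("`rho` must be > 0 wherever evaluated")
    rho_eval <- matrix(rho, d[1], d[2])
  }
  denom <- if (field_convention == "peak") 2 else 1
  sar <- map$sigma * e_cell^2 / (denom * rho_eval)
  sar[!tissue] <- NA_real_
  cx <- axis_coords(d[1], map$spacing[1], map$origin[1])
  cy <- axis_coords(d[2], map$spacing[2], map$origin[2])
  structure(
    list(sar = sar, labels = map$labels, spacing = map$spacing,
         coords = list(cx, cy), axes = map$axes, rho = rho,
         frequency = field$frequency,
         field_convention = field_convention),
    class = "sar_map"
  )
}

#' @export
print.sar_map <- function(x, ...) {
  cat("<sar_map> peak ", signif(max(x$sar, na.rm = TRUE), 4),
      " W/kg over ", sum(!is.na(x$sar)), " tissue cells\n", sep = "")
  invisible(x)
}

#' Peak local SAR and safety verdict
#'
#' Reports the maximum local SAR, its location and tissue label, and whether
#' it is below the exposure limit (2 W/kg averaged over 10 g of tissue in the
#' IEEE/ICNIRP guidelines; a local maximum at or below the limit bounds every
#' 10 g average from above, so the local check is conservative).
#'
#' @param sar A `sar_map`.
#' @param limit Safety limit in W/kg.
#' @return One-row tibble: `peak_sar`, location (mm), `tissue_id`, `tissue`,
#'   `limit`, `pass`.
#' @export
peak_and_check <- function(sar, limit = 2) {
  stopifnot(inherits(sar, "sar_map"))
  if (all(is.na(sar$sar))) stop("SAR map has no tissue cells")
  vals <- sar$sar
  if (max(vals, na.rm = TRUE) == 0) {
    pk_val <- 0
    idx <- which(!is.na(vals))[1]
  } else {
    idx <- which.max(ifelse(is.na(vals), -Inf, vals))
    pk_val <- vals[idx]
  }
  pk <- arrayInd(idx, dim(vals))
  tid <- sar$labels[pk]
  ct <- canonical_tissues()
  tname <- ct$tissue[match(tid, ct$canonical_id)]
  if (is.na(tname) && tid %in% STROKE_ID) {
    tname <- paste0("stroke (", names(STROKE_ID)[match(tid, STROKE_ID)], ")")
  }
  out <- tibble::tibble(
    peak_sar = pk_val,
    x = sar$coords[[1]][pk[1]],
    y = sar$coords[[2]][pk[2]],
    tissue_id = as.integer(tid),
    tissue = tname,
    limit = limit,
    pass = pk_val < limit
  )
  names(out)[2:3] <- sar$axes
  out
}

#' Mass-averaged SAR (square-window analog of the 10 g cube)
#'
#' Optional averaging operation: each cell gets the mean SAR over a square
#' window whose side is the edge of a cube containing `mass_g` grams at the
#' map's density -- the per-slice analog of volumetric 10 g averaging. Air
#' cells contribute neither mass nor power.
#'
#' @param sar A `sar_map`.
#' @param mass_g Averaging mass in grams.
#' @return A `sar_map` whose `sar` matrix holds the windowed averages.
#' @export
sar_mass_average <- function(sar, mass_g = 10) {
  stopifnot(inherits(sar, "sar_map"))
  rho <- if (is.matrix(sar$rho)) mean(sar$rho) else sar$rho
  side_mm <- (mass_g / 1000 / rho)^(1 / 3) * 1000
  half <- max(1L, round(side_mm / 2 / mean(sar$spacing)))
  v <- sar$sar
  d <- dim(v)
  filled <- ifelse(is.na(v), 0, v)
  cnt <- ifelse(is.na(v), 0, 1)
  # summed-area tables for the moving window: S[i, j] = sum m[1..i, 1..j]
  sat <- function(m) t(apply(apply(m, 2, cumsum), 1, cumsum))
  Sv <- sat(filled); Sc <- sat(cnt)
  win_sum <- function(S, i0, i1, j0, j1) {
    S[cbind(i1, j1)] -
      ifelse(i0 > 1, S[cbind(pmax(i0 - 1, 1), j1)], 0) -
      ifelse(j0 > 1, S[cbind(i1, pmax(j0 - 1, 1))], 0) +
      ifelse(i0 > 1 & j0 > 1, S[cbind(pmax(i0 - 1, 1), pmax(j0 - 1, 1))], 0)
  }
  out <- v
  ii <- rep(seq_len(d[1]), times = d[2])
  jj <- rep(seq_len(d[2]), each = d[1])
  i0 <- pmax(ii - half, 1L); i1 <- pmin(ii + half, d[1])
  j0 <- pmax(jj - half, 1L); j1 <- pmin(jj + half, d[2])
  tot <- win_sum(Sv, i0, i1, j0, j1)
  n <- win_sum(Sc, i0, i1, j0, j1)
  avg <- ifelse(n > 0, tot / n, NA_real_)
  out[] <- avg
  out[is.na(v)] <- NA_real_
  res <- sar
  res$sar <- out
  res
}

#' Tidy a SAR map into a long tibble
#'
#' @param x A `sar_map`.
#' @param ... Unused.
#' @return Tibble with cell-centre coordinates and `sar` (air cells dropped).
#' @export
tidy.sar_map <- function(x, ...) {
  d <- dim(x$sar)
  out <- tibble::tibble(
    a = rep(x$coords[[1]], times = d[2]),
    b = rep(x$coords[[2]], each = d[1]),
    sar = as.numeric(x$sar)
  )
  names(out)[1:2] <- x$axes
  out[!is.na(out$sar), ]
}

#' Plot a SAR map on a thermal colour scale
#'
#' @param object A `sar_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sar_map <- function(object, ...) {
  df <- tidy.sar_map(object)
  nms <- names(df)
  ggplot2::ggplot(df, ggplot2::aes(.data[[nms[1]]], .data[[nms[2]]],
                                   fill = .data$sar)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_distiller(palette = "YlOrBr", direction = 1,
                                  name = "SAR (W/kg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(nms[1], "(mm)"), y = paste(nms[2], "(mm)")) +
    ggplot2::theme_minimal()
}
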