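#' Construct a voxel phantom
#'
#' A voxel phantom is a 3D integer label grid with physical voxel spacing (mm)
#' and an origin placed at the grid centre, so voxel-centre coordinates are
#' symmetric about the head centroid. The +y axis points toward the face, so a
#' frontal stroke centre such as (0, -70, 26.6) mm sits anterior.
#'
#' @param labels 3D integer array of tissue labels.
#' @param spacing Numeric length-3, voxel size (dx, dy, dz) in mm; all > 0.
#' @param origin Numeric length-3, physical coordinate (mm) of the grid centre.
#' @param label_vocab Named integer vector of valid labels (names are tissue
#'   names). Defaults to the labels present in `labels`.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, spacing, origin = c(0, 0, 0),
                          label_vocab = NULL) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (any(dim(labels) < 1L)) stop("grid dimensions must be >= 1 on each axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel sizes in mm")
  }
  storage.mode(labels) <- "integer"
  if (is.null(label_vocab)) {
    ids <- sort(unique(as.integer(labels)))
    label_vocab <- stats::setNames(ids, paste0("label_", ids))
  }
  bad <- setdiff(unique(as.integer(labels)), as.integer(label_vocab))
  if (length(bad)) {
    stop("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin),
         label_vocab = label_vocab),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("<voxel_phantom> ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  tb <- table(x$labels)
  cat("  labels:", paste0(names(tb), " (", as.integer(tb), ")", collapse = ", "),
      "\n")
  invisible(x)
}

# voxel-centre coordinates along one axis (mm), symmetric about the origin
axis_coords <- function(n, h, origin0) origin0 + (seq_len(n) - (n + 1) / 2) * h

#' Voxel-centre coordinate vectors of a phantom
#'
#' @param phantom A [voxel_phantom()].
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
phantom_coords <- function(phantom) {
  d <- dim(phantom$labels)
  list(
    x = axis_coords(d[1], phantom$spacing[1], phantom$origin[1]),
    y = axis_coords(d[2], phantom$spacing[2], phantom$origin[2]),
    z = axis_coords(d[3], phantom$spacing[3], phantom$origin[3])
  )
}

#' Default shell geometry of the synthetic layered head
#'
#' Seven nested ellipsoidal tissue shells (outermost to innermost: skin, fat,
#' cortical bone, CSF, dura, grey matter, white matter) with an outer shell of
#' approximately 90 x 110 x 120 mm semi-axes -- an adult-head scale consistent
#' with a 3-4 cm antenna standoff.
#'
#' @return Named list of semi-axis triples (mm), outermost first.
#' @export
default_head_shells <- function() {
  list(
    `skin (dry)` = c(90, 110, 120),
    fat = c(86, 106, 116),
    `bone, cortical` = c(82, 102, 112),
    `cerebrospinal fluid (CSF)` = c(75, 95, 105),
    dura = c(72, 92, 102),
    `grey matter (GM)` = c(70, 90, 100),
    `white matter (WM)` = c(50, 65, 75)
  )
}

default_shell_ids <- function() {
  c(TISSUE_ID[["skin"]], TISSUE_ID[["fat"]], TISSUE_ID[["bone"]],
    TISSUE_ID[["csf"]], TISSUE_ID[["dura"]], TISSUE_ID[["gm"]],
    TISSUE_ID[["wm"]])
}

head_label_vocab <- function() {
  ct <- canonical_tissues()
  vocab <- stats::setNames(ct$canonical_id, ct$tissue)
  c(vocab, stats::setNames(as.integer(STROKE_ID),
                           paste0("stroke (", names(STROKE_ID), ")")))
}

#' Generate a synthetic layered head phantom
#'
#' Builds a voxel phantom of strictly nested ellipsoidal tissue shells on a
#' regular grid. Each voxel takes the label of the innermost shell containing
#' its centre; voxels outside all shells are air. The construction is
#' deterministic for fixed arguments and mirror-symmetric about planes through
#' the origin when all shells are origin-centred.
#'
#' @param shell_semi_axes Named list of semi-axis triples (mm), ordered
#'   outermost to innermost; see [default_head_shells()].
#' @param spacing Voxel size (mm), length 1 or 3.
#' @param grid_dims Integer grid dimensions; `NULL` sizes the grid to the outer
#'   shell plus one voxel margin (odd counts, so a voxel centre sits at the
#'   origin).
#' @param shell_ids Integer labels for the shells, same length/order as
#'   `shell_semi_axes`.
#' @return A [voxel_phantom()] whose vocabulary is the canonical tissue set.
#' @export
#' @examples
#' ph <- generate_layered_head(spacing = 4)
#' table(ph$labels)
generate_layered_head <- function(shell_semi_axes = default_head_shells(),
                                  spacing = c(2, 2, 2),
                                  grid_dims = NULL,
                                  shell_ids = default_shell_ids()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(shell_semi_axes) == length(shell_ids))
  ax <- lapply(shell_semi_axes, function(a) {
    a <- as.numeric(a)
    if (length(a) != 3L || any(a < 0)) stop("semi-axes must be 3 values >= 0")
    a
  })
  nm <- names(ax)
  if (is.null(nm)) nm <- paste0("shell_", seq_along(ax))
  if (length(ax) > 1L) {
    for (k in seq_len(length(ax) - 1L)) {
      if (!all(ax[[k + 1L]] < ax[[k]] | (ax[[k + 1L]] == 0 & ax[[k]] == 0))) {
        stop("shells not strictly nested: '", nm[k + 1L],
             "' is not componentwise inside '", nm[k], "'")
      }
    }
  }
  outer_ax <- ax[[1L]]
  if (is.null(grid_dims)) {
    grid_dims <- 2L * ceiling(outer_ax / spacing + 1) + 1L  # odd, centred
  }
  grid_dims <- as.integer(grid_dims)
  if (any(grid_dims < 1L)) stop("grid dimensions must be >= 1 on each axis")
  half_extent <- (grid_dims - 1) / 2 * spacing
  if (any(outer_ax > half_extent + spacing / 2) && any(outer_ax > 0)) {
    warning("grid too small to contain the outer shell; shells clipped")
  }

  xs <- axis_coords(grid_dims[1], spacing[1], 0)
  ys <- axis_coords(grid_dims[2], spacing[2], 0)
  zs <- axis_coords(grid_dims[3], spacing[3], 0)
  labels <- array(TISSUE_ID[["air"]], dim = grid_dims)
  # outermost to innermost, overwriting: final label = innermost containing shell
  for (k in seq_along(ax)) {
    a <- ax[[k]]
    if (any(a <= 0)) next                      # degenerate shell: no voxels
    rx2 <- (xs / a[1])^2
    ry2 <- (ys / a[2])^2
    rz2 <- (zs / a[3])^2
    q <- outer(rx2, ry2, "+")
    inside <- outer(q, rz2, "+") <= 1
    labels[inside] <- shell_ids[k]
  }
  voxel_phantom(labels, spacing, origin = c(0, 0, 0),
                label_vocab = head_label_vocab())
}

#' Read a raw voxel phantom (flat binary uint8 dialect)
#'
#' Reads a flat binary file of unsigned 8-bit tissue labels in x-fastest order
#' (x varies fastest, then y, then z), the common distribution dialect for
#' segmented MRI label grids such as the 256 x 256 x 128 head phantom with
#' 1.1 x 1.1 x 1.4 mm voxels. Grid dimensions and spacing are supplied, never
#' inferred.
#'
#' @param path File path.
#' @param dims Integer length-3 grid dimensions.
#' @param spacing Voxel size (mm), length 1 or 3.
#' @param origin Physical coordinate (mm) of the grid centre.
#' @param label_vocab Optional named integer vocabulary; defaults to the
#'   labels present in the file.
#' @return A [voxel_phantom()].
#' @export
read_voxel_phantom <- function(path, dims, spacing, origin = c(0, 0, 0),
                               label_vocab = NULL) {
  dims <- as.integer(dims)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  expected <- prod(as.double(dims))
  actual <- file.info(path)$size
  if (is.na(actual) || actual != expected) {
    stop(sprintf("file size mismatch: expected %.0f bytes for dims %s, found %.0f",
                 expected, paste(dims, collapse = "x"),
                 ifelse(is.na(actual), 0, actual)))
  }
  raw <- readBin(path, what = "raw", n = expected)
  labels <- array(as.integer(raw), dim = dims)   # column-major = x-fastest
  voxel_phantom(labels, spacing, origin, label_vocab)
}

#' Write a voxel phantom as flat binary uint8
#'
#' Inverse of [read_voxel_phantom()]; round-trips bit-exactly.
#'
#' @param phantom A [voxel_phantom()] with labels in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voxel_phantom <- function(phantom, path) {
  v <- as.integer(phantom$labels)
  if (any(v < 0L | v > 255L)) stop("labels outside uint8 range 0..255")
  writeBin(as.raw(v), path)
  invisible(path)
}

#' Read a tissue-mapping table
#'
#' @param path CSV with columns `source_id`, `canonical_name`, `canonical_id`,
#'   `model_tag`. Defaults to the synthetic 60-to-21 mapping shipped with the
#'   package (a stand-in constructed with the published partition: 56 source
#'   types carry the fourth-order Debye tag, 4 the fourth-order Cole-Cole tag).
#' @return A tibble.
#' @export
read_tissue_map <- function(path = system.file("extdata",
                                               "tissue_map_synthetic.csv",
                                               package = "mwihead")) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("source_id", "canonical_name", "canonical_id", "model_tag")
  if (!all(need %in% names(tb))) {
    stop("tissue map must have columns ", paste(need, collapse = ", "))
  }
  tb
}

#' Map source tissue labels to the 21 canonical classes
#'
#' Applies a source-ID to canonical-ID mapping to every voxel. Voxel counts
#' are conserved per mapping fibre: the number of voxels mapped onto canonical
#' class k equals the summed counts of all source labels mapping to k.
#'
#' @param phantom A [voxel_phantom()].
#' @param table Mapping tibble as from [read_tissue_map()].
#' @return A [voxel_phantom()] using only canonical IDs.
#' @export
map_tissues <- function(phantom, table = read_tissue_map()) {
  present <- unique(as.integer(phantom$labels))
  missing <- setdiff(present, table$source_id)
  if (length(missing)) {
    stop("no mapping entry for source label(s): ",
         paste(sort(missing), collapse = ", "))
  }
  lut <- rep(NA_integer_, max(table$source_id))
  lut[table$source_id] <- as.integer(table$canonical_id)
  mapped <- array(lut[as.integer(phantom$labels)], dim = dim(phantom$labels))
  voxel_phantom(mapped, phantom$spacing, phantom$origin,
                label_vocab = head_label_vocab())
}

#' Specify a spherical stroke
#'
#' @param kind `"haemorrhagic"`, `"ischaemic"` or `"none"` (the normal-brain
#'   control: the sphere keeps the underlying healthy labels).
#' @param centre Stroke centre (x, y, z) in mm.
#' @param radius Sphere radius in mm (> 0).
#' @param override Optional `c(eps_r, sigma)` dielectric override; defaults to
#'   [stroke_defaults()] for the given kind.
#' @return An object of class `stroke_spec`.
#' @export
#' @examples
#' stroke_spec("haemorrhagic", centre = c(0, -70, 26.6), radius = 10)
stroke_spec <- function(kind = c("none", "haemorrhagic", "ischaemic"),
                        centre = c(0, 0, 0), radius = 10, override = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.null(override) && length(override) != 2L) {
    stop("`override` must be c(eps_r, sigma)")
  }
  structure(list(kind = kind, centre = as.numeric(centre),
                 radius = as.numeric(radius), override = override),
            class = "stroke_spec")
}

# squared distance of every voxel centre to a point (mm^2)
voxel_dist2 <- function(phantom, centre) {
  co <- phantom_coords(phantom)
  dx2 <- (co$x - centre[1])^2
  dy2 <- (co$y - centre[2])^2
  dz2 <- (co$z - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Insert a spherical stroke into a phantom
#'
#' Voxels whose centres lie within `radius` of `centre` and that are not air
#' receive the stroke label (a stroke is intracranial by definition, so air is
#' never overwritten). `kind = "none"` returns the phantom unchanged. The
#' operation is idempotent for identical specs.
#'
#' @param phantom A [voxel_phantom()].
#' @param spec A [stroke_spec()].
#' @return A [voxel_phantom()] with the stroke label applied.
#' @export
insert_stroke <- function(phantom, spec) {
  stopifnot(inherits(spec, "stroke_spec"))
  if (spec$kind == "none") return(phantom)
  inside <- voxel_dist2(phantom, spec$centre) <= spec$radius^2
  nonair <- phantom$labels != TISSUE_ID[["air"]]
  hit <- inside & nonair
  if (!any(hit)) stop("stroke outside head: sphere contains no tissue voxel")
  labels <- phantom$labels
  labels[hit] <- STROKE_ID[[spec$kind]]
  vocab <- phantom$label_vocab
  sid <- STROKE_ID[[spec$kind]]
  if (!sid %in% vocab) vocab <- c(vocab, stats::setNames(sid, paste0("stroke (", spec$kind, ")")))
  voxel_phantom(labels, phantom$spacing, phantom$origin, vocab)
}

#' Extract a 2D slice from a voxel phantom
#'
#' Returns the plane of the 3D grid at the given index along `axis`, with
#' in-plane physical coordinates preserved.
#'
#' @param phantom A [voxel_phantom()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param index 1-based slice index along `axis`.
#' @return An object of class `phantom_slice`: 2D label matrix plus in-plane
#'   `spacing`, `origin`, axis names and the fixed-axis coordinate.
#' @export
extract_slice <- function(phantom, axis = c("z", "x", "y"), index) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  d <- dim(phantom$labels)
  if (index < 1L || index > d[ai]) {
    stop(sprintf("slice index %d out of range [1, %d] on axis %s",
                 index, d[ai], axis))
  }
  keep <- setdiff(1:3, ai)
  labels <- switch(axis,
    x = phantom$labels[index, , ],
    y = phantom$labels[, index, ],
    z = phantom$labels[, , index]
  )
  co <- phantom_coords(phantom)
  structure(
    list(labels = labels,
         spacing = phantom$spacing[keep],
         origin = phantom$origin[keep],
         axes = c("x", "y", "z")[keep],
         fixed_axis = axis,
         fixed_coord = co[[axis]][index],
         label_vocab = phantom$label_vocab),
    class = "phantom_slice"
  )
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat("<phantom_slice> ", paste(dim(x$labels), collapse = " x "),
      " (", paste(x$axes, collapse = ","), ") at ", x$fixed_axis, " = ",
      signif(x$fixed_coord, 4), " mm\n", sep = "")
  invisible(x)
}

#' Slice index closest to a physical coordinate
#'
#' @param phantom A [voxel_phantom()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param coord Physical coordinate in mm.
#' @return Integer slice index.
#' @export
slice_index_at <- function(phantom, axis = c("z", "x", "y"), coord) {
  axis <- match.arg(axis)
  which.min(abs(phantom_coords(phantom)[[axis]] - coord))
}

#' In-plane coordinate vectors of a slice
#'
#' @param slice A `phantom_slice`.
#' @return List with the two in-plane coordinate vectors (mm), named by axis.
#' @export
slice_coords <- function(slice) {
  d <- dim(slice$labels)
  out <- list(
    axis_coords(d[1], slice$spacing[1], slice$origin[1]),
    axis_coords(d[2], slice$spacing[2], slice$origin[2])
  )
  names(out) <- slice$axes
  out
}

#' Embed a slice in a larger air region
#'
#' Pads a head slice with air so that an antenna array and absorbing boundary
#' layers fit inside the computational domain. The physical origin is
#' preserved (padding is symmetric up to one voxel).
#'
#' @param slice A `phantom_slice`.
#' @param half_extent Target half-width (mm) of the padded domain per in-plane
#'   axis, length 1 or 2.
#' @return A `phantom_slice` with enlarged label grid.
#' @export
embed_slice <- function(slice, half_extent) {
  if (length(half_extent) == 1L) half_extent <- rep(half_extent, 2)
  d <- dim(slice$labels)
  newd <- pmax(d, 2L * ceiling(half_extent / slice$spacing) + 1L)
  pad_lo <- (newd - d) %/% 2L
  labels <- matrix(TISSUE_ID[["air"]], newd[1], newd[2])
  labels[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2])] <- slice$labels
  # keep voxel centres aligned: shift origin if padding is uneven
  shift <- ((newd - d) / 2 - pad_lo) * slice$spacing
  out <- slice
  out$labels <- labels
  out$origin <- slice$origin - shift
  out
}

#' Tidy a voxel phantom or slice into a long tibble
#'
#' @param x A `voxel_phantom` or `phantom_slice`.
#' @param ... Unused.
#' @return A tibble with voxel-centre coordinates (mm) and the integer label.
#' @export
tidy.voxel_phantom <- function(x, ...) {
  co <- phantom_coords(x)
  d <- dim(x$labels)
  tibble::tibble(
    x = rep(co$x, times = d[2] * d[3]),
    y = rep(rep(co$y, each = d[1]), times = d[3]),
    z = rep(co$z, each = d[1] * d[2]),
    label = as.integer(x$labels)
  )
}

#' @rdname tidy.voxel_phantom
#' @export
tidy.phantom_slice <- function(x, ...) {
  co <- slice_coords(x)
  d <- dim(x$labels)
  out <- tibble::tibble(
    a = rep(co[[1]], times = d[2]),
    b = rep(co[[2]], each = d[1]),
    label = as.integer(x$labels)
  )
  names(out)[1:2] <- x$axes
  out
}

#' Plot a phantom slice
#'
#' @param object A `phantom_slice`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_slice <- function(object, ...) {
  df <- tidy.phantom_slice(object)
  nms <- names(df)
  ggplot2::ggplot(df, ggplot2::aes(.data[[nms[1]]], .data[[nms[2]]],
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "label", x = paste(nms[1], "(mm)"),
                  y = paste(nms[2], "(mm)")) +
    ggplot2::theme_minimal()
}
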