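#' Define a frequency-domain Helmholtz scattering problem
#'
#' Bundles a dielectric map (2D slice or coarse 3D), the operating frequency,
#' the antenna feed sources and the PML settings. Tissues are non-magnetic
#' (`mu_r = 1` everywhere). The scalar equation solved is the TMz reduction of
#' the curl-curl wave equation,
#' \deqn{\nabla\cdot(\mu_r^{-1}\nabla E_z) + k_0^2\left(\varepsilon_r -
#'   j\frac{\sigma}{\omega\varepsilon_0}\right) E_z = j\omega\mu_0 J_z,}
#' with complex coordinate stretching inside the PML and a homogeneous
#' Dirichlet condition on the outer boundary. Continuity of the tangential
#' field across material interfaces is natural for nodal elements.
#'
#' @param dielectric A `dielectric_map` (2D or 3D).
#' @param sources A data frame with columns `x`, `y` (and `z` in 3D) in mm and
#'   `amplitude` (complex line/point current in A). Sources must lie strictly
#'   inside the non-PML region.
#' @param frequency Frequency in Hz; defaults to the map's frequency.
#' @param pml A [pml_spec()].
#' @param pml_axes Axes carrying a PML (others get a reflecting Neumann
#'   boundary); default all axes. Only the 3D assembly honours a reduced set.
#' @return An object of class `helmholtz_problem`.
#' @export
helmholtz_problem <- function(dielectric, sources, frequency = dielectric$frequency,
                              pml = pml_spec(), pml_axes = NULL) {
  stopifnot(inherits(dielectric, "dielectric_map"))
  if (length(dielectric$eps_r) == 0L) stop("empty dielectric map")
  if (frequency <= 0) stop("`frequency` must be > 0")
  sources <- tibble::as_tibble(sources)
  nd <- length(dim(dielectric$eps_r))
  need <- c("x", "y", if (nd == 3L) "z", "amplitude")
  if (!all(need %in% names(sources)) || nrow(sources) == 0L) {
    stop("`sources` needs at least one row with columns ",
         paste(need, collapse = ", "))
  }
  if (is.null(pml_axes)) pml_axes <- c("x", "y", "z")[seq_len(nd)]
  structure(list(dielectric = dielectric, sources = sources,
                 frequency = frequency, mu_r = 1, pml = pml,
                 pml_axes = pml_axes),
            class = "helmholtz_problem")
}

# ---- complex CSC container ---------------------------------------------------
# (p, i) are 0-based dgCMatrix-style arrays; all operators assembled here are
# complex symmetric, so (p, i, x) double as a CSR representation for the
# compiled kernels.

new_csc <- function(n, p, i, x) {
  structure(list(n = n, p = p, i = i, x = x), class = "csc_cplx")
}

csc_matvec <- function(A, v) csr_matvec(A$p, A$i, A$x, v)

# aggregate triplets (ti, tj, columns of complex values) into one shared
# CSC pattern; returns list(p, i, xs = list of complex vectors)
aggregate_triplets <- function(ti, tj, xs, n) {
  key <- (tj - 1) * n + ti                   # column-major order
  vals <- do.call(cbind, lapply(xs, function(x) cbind(Re(x), Im(x))))
  agg <- rowsum(vals, group = key, reorder = TRUE)
  ukey <- as.numeric(rownames(agg))
  i_agg <- as.integer((ukey - 1) %% n)                 # 0-based rows
  j_agg <- as.integer((ukey - 1) %/% n) + 1L           # 1-based cols
  p <- c(0L, cumsum(tabulate(j_agg, nbins = n)))
  out_x <- lapply(seq_along(xs), function(k) {
    complex(real = agg[, 2 * k - 1], imaginary = agg[, 2 * k])
  })
  list(p = as.integer(p), i = i_agg, xs = out_x)
}

# real-equivalent sparse matrix [[Ar, -Ai], [Ai, Ar]] for direct solves
csc_real_equivalent <- function(A) {
  n <- A$n
  j <- rep(seq_len(n), diff(A$p))
  i <- A$i + 1L
  xr <- Re(A$x); xi <- Im(A$x)
  Matrix::sparseMatrix(
    i = c(i, i + n, i, i + n),
    j = c(j, j + n, j + n, j),
    x = c(xr, xr, -xi, xi),
    dims = c(2L * n, 2L * n)
  )
}

node_grid_coords <- function(map) {
  d <- dim(map$eps_r)
  lapply(seq_along(d), function(a) {
    # node a-coordinates: cell boundaries, spacing h, centred on origin
    h <- map$spacing[a]
    map$origin[a] + (0:d[a] - d[a] / 2) * h
  })
}

check_sources_interior <- function(sources, profiles, axes) {
  for (a in seq_along(axes)) {
    v <- sources[[axes[a]]]
    box <- profiles[[a]]$interior
    if (any(v <= box[1] | v >= box[2])) {
      stop("source lies inside the PML region on axis ", axes[a])
    }
  }
}

#' Assemble the 2D TMz Helmholtz system (P1 finite elements)
#'
#' Discretizes the scalar TMz Helmholtz equation on a structured triangulation
#' of the cell grid (each rectangular cell split into two first-order
#' triangles), with per-cell piecewise-constant dielectric coefficients and
#' anisotropic stretched-coordinate PML coefficients. Boundary nodes (Dirichlet
#' zero behind the PML) are eliminated. The resulting matrix is complex
#' symmetric (equal to its transpose, not its conjugate transpose).
#'
#' @param problem A [helmholtz_problem()] with a 2D dielectric map.
#' @return An object of class `helmholtz_system` with the stiffness-minus-mass
#'   operator `A`, the mass-term values `Mx` (for shifted preconditioning), the
#'   right-hand side `b`, and mesh metadata.
#' @export
assemble_2d <- function(problem) {
  stopifnot(inherits(problem, "helmholtz_problem"))
  map <- problem$dielectric
  d <- dim(map$eps_r)
  if (length(d) != 2L) stop("assemble_2d() needs a 2D dielectric map")
  nx <- d[1]; ny <- d[2]
  k <- physical_constants()
  w <- 2 * pi * problem$frequency
  k0 <- w / k$c
  hx <- map$spacing[1] / 1000; hy <- map$spacing[2] / 1000   # metres

  nodes <- node_grid_coords(map)                              # mm
  profiles <- make_pml(nodes, problem$pml, problem$frequency)
  check_sources_interior(problem$sources, profiles, map$axes)

  cx <- (nodes[[1]][-1] + nodes[[1]][-(nx + 1)]) / 2          # cell centres, mm
  cy <- (nodes[[2]][-1] + nodes[[2]][-(ny + 1)]) / 2
  sx <- profiles[[1]]$s(cx)                                   # per-cell stretch
  sy <- profiles[[2]]$s(cy)

  eps_c <- map_complex_eps(map)
  SX <- matrix(sx, nx, ny)
  SY <- matrix(sy, nx, ny, byrow = TRUE)
  ax <- as.vector(SY / SX)            # coefficient on d/dx flux
  ay <- as.vector(SX / SY)            # coefficient on d/dy flux
  qq <- as.vector(k0^2 * eps_c * SX * SY)

  # node index grid, 1-based, x fastest
  Nx1 <- nx + 1L
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  n00 <- ii + (jj - 1L) * Nx1
  n10 <- n00 + 1L
  n01 <- n00 + Nx1
  n11 <- n01 + 1L

  # local matrices for the two triangles of a cell with size hx x hy
  # T1 = (n00, n10, n11), T2 = (n00, n11, n01)
  gx <- hy / (2 * hx); gy <- hx / (2 * hy); A2 <- hx * hy / 2
  B1x <- matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3, 3)
  B1y <- matrix(c(0, 0, 0, 0, 1, -1, 0, -1, 1), 3, 3)
  B2x <- B1y
  B2y <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3)
  Mloc <- (A2 / 12) * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3)
  tri_nodes <- list(cbind(n00, n10, n11), cbind(n00, n11, n01))
  Bx <- list(B1x, B2x); By <- list(B1y, B2y)

  ncell <- nx * ny
  tlist_i <- tlist_j <- vector("list", 18L)
  tlist_k <- tlist_m <- vector("list", 18L)
  idx <- 1L
  for (t in 1:2) {
    nd3 <- tri_nodes[[t]]
    for (a in 1:3) for (bcol in 1:3) {
      tlist_i[[idx]] <- nd3[, a]
      tlist_j[[idx]] <- nd3[, bcol]
      tlist_k[[idx]] <- gx * Bx[[t]][a, bcol] * ax + gy * By[[t]][a, bcol] * ay
      tlist_m[[idx]] <- Mloc[a, bcol] * qq
      idx <- idx + 1L
    }
  }
  ti <- unlist(tlist_i); tj <- unlist(tlist_j)
  xk <- unlist(tlist_k); xm <- unlist(tlist_m)

  # eliminate Dirichlet boundary nodes before aggregation
  nnode <- Nx1 * (ny + 1L)
  bx <- rep(seq_len(Nx1), times = ny + 1L)
  by <- rep(seq_len(ny + 1L), each = Nx1)
  interior <- which(bx > 1L & bx < Nx1 & by > 1L & by < ny + 1L)
  remap <- rep(NA_integer_, nnode)
  remap[interior] <- seq_along(interior)
  keep <- !is.na(remap[ti]) & !is.na(remap[tj])
  n_int <- length(interior)
  agg <- aggregate_triplets(remap[ti[keep]], remap[tj[keep]],
                            list(K = xk[keep], M = xm[keep]), n_int)
  Ax <- agg$xs[[1]] - agg$xs[[2]]
  A <- new_csc(n_int, agg$p, agg$i, Ax)

  # delta feed sources at their exact physical position, spread bilinearly
  # onto the four surrounding nodes (weak-form load -j w mu0 I phi(x_s));
  # keeps the source location mesh-independent across refinement ladders
  b <- complex(n_int)
  src_nodes <- integer(nrow(problem$sources))
  for (s in seq_len(nrow(problem$sources))) {
    px <- problem$sources[[map$axes[1]]][s]
    py <- problem$sources[[map$axes[2]]][s]
    isx <- min(max(findInterval(px, nodes[[1]]), 1L), nx)
    isy <- min(max(findInterval(py, nodes[[2]]), 1L), ny)
    tx <- (px - nodes[[1]][isx]) / (nodes[[1]][isx + 1L] - nodes[[1]][isx])
    ty <- (py - nodes[[2]][isy]) / (nodes[[2]][isy + 1L] - nodes[[2]][isy])
    gns <- c(isx + (isy - 1L) * Nx1, isx + 1L + (isy - 1L) * Nx1,
             isx + isy * Nx1, isx + 1L + isy * Nx1)
    wts <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
    use <- wts > 1e-12
    if (any(is.na(remap[gns[use]]))) stop("source on the Dirichlet boundary")
    load <- -1i * w * k$mu0 * problem$sources$amplitude[s]
    b[remap[gns[use]]] <- b[remap[gns[use]]] + load * wts[use]
    src_nodes[s] <- remap[gns[use][which.max(wts[use])]]
  }

  structure(
    list(A = A, Mx = agg$xs[[2]], b = b, dof = n_int,
         node_dim = c(Nx1, ny + 1L), interior = interior,
         node_coords = nodes, spacing = map$spacing,
         frequency = problem$frequency, k0 = k0,
         dielectric = map, sources = problem$sources,
         src_nodes = src_nodes, pml = profiles, kind = "fem2d"),
    class = "helmholtz_system"
  )
}

#' @export
print.helmholtz_system <- function(x, ...) {
  cat("<helmholtz_system> ", x$kind, ", ", x$dof, " complex DOF at ",
      signif(x$frequency / 1e9, 4), " GHz\n", sep = "")
  invisible(x)
}

#' Assemble a coarse 3D scalar Helmholtz system (7-point finite differences)
#'
#' Second-order finite-difference discretization of the 3D scalar Helmholtz
#' operator on the voxel grid, with stretched-coordinate PML. Each equation is
#' scaled by `sx sy sz` so the operator stays complex symmetric. Axes listed in
#' `pml_axes` end in a Dirichlet wall behind the PML; other axes get reflecting
#' Neumann boundaries (so a z-invariant slab with a z-line source reproduces
#' the 2D physics along every z-line).
#'
#' @param problem A [helmholtz_problem()] with a 3D dielectric map.
#' @param dof_cap Maximum number of unknowns (default 2e6).
#' @param line_source_z If `TRUE`, each source row is applied as a z-line
#'   source through all z-nodes at its (x, y).
#' @return A `helmholtz_system`.
#' @export
assemble_3d_scalar <- function(problem, dof_cap = 2e6, line_source_z = FALSE) {
  stopifnot(inherits(problem, "helmholtz_problem"))
  map <- problem$dielectric
  d <- dim(map$eps_r)
  if (length(d) != 3L) stop("assemble_3d_scalar() needs a 3D dielectric map")
  k <- physical_constants()
  w <- 2 * pi * problem$frequency
  k0 <- w / k$c
  h <- map$spacing / 1000

  # unknowns live on cell centres here (node = voxel centre)
  co <- list(axis_coords(d[1], map$spacing[1], map$origin[1]),
             axis_coords(d[2], map$spacing[2], map$origin[2]),
             axis_coords(d[3], map$spacing[3], map$origin[3]))
  pml_axes <- problem$pml_axes
  profiles <- vector("list", 3)
  for (a in 1:3) {
    ax_name <- c("x", "y", "z")[a]
    if (ax_name %in% pml_axes) {
      profiles[[a]] <- make_pml(list(co[[a]]), problem$pml,
                                problem$frequency)[[1]]
    } else {
      profiles[[a]] <- list(s = function(x) rep(1 + 0i, length(x)),
                            interior = range(co[[a]]))
    }
  }
  check_sources_interior(problem$sources[c("x", "y")], profiles[1:2],
                         c("x", "y"))

  dirichlet <- c("x", "y", "z") %in% pml_axes
  n_unknown <- prod(d - ifelse(dirichlet, 2L, 0L))
  if (n_unknown > dof_cap) {
    stop(sprintf("3D system would have %.3g unknowns, above the cap %.3g; coarsen the grid",
                 n_unknown, dof_cap))
  }

  s_node <- lapply(1:3, function(a) profiles[[a]]$s(co[[a]]))
  s_half <- lapply(1:3, function(a) {
    profiles[[a]]$s((co[[a]][-1] + co[[a]][-d[a]]) / 2)
  })

  eps_c <- map_complex_eps(map)
  Sx <- array(rep(s_node[[1]], times = d[2] * d[3]), d)
  Sy <- array(rep(rep(s_node[[2]], each = d[1]), times = d[3]), d)
  Sz <- array(rep(s_node[[3]], each = d[1] * d[2]), d)
  Svol <- Sx * Sy * Sz

  lin <- function(i, j, l) i + (j - 1L) * d[1] + (l - 1L) * d[1] * d[2]
  ii <- rep(seq_len(d[1]), times = d[2] * d[3])
  jj <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  ll <- rep(seq_len(d[3]), each = d[1] * d[2])
  centre <- lin(ii, jj, ll)

  ti <- tj <- integer(0); tx <- complex(0)
  diag_acc <- complex(length(centre))
  add_axis <- function(a) {
    idx3 <- list(ii, jj, ll)[[a]]
    s_n <- list(Sx, Sy, Sz)[[a]]
    svol_over <- Svol / s_n                # s_b s_c for the flux coefficient
    # neighbour in +a direction
    has_p <- idx3 < d[a]
    shalf_p <- s_half[[a]][pmin(idx3, d[a] - 1L)]
    cp <- svol_over / (shalf_p * h[a]^2)
    # neighbour in -a direction
    has_m <- idx3 > 1L
    shalf_m <- s_half[[a]][pmax(idx3 - 1L, 1L)]
    cm <- svol_over / (shalf_m * h[a]^2)
    off <- c(1L, d[1], d[1] * d[2])[a]
    ti <<- c(ti, centre[has_p], centre[has_m])
    tj <<- c(tj, centre[has_p] + off, centre[has_m] - off)
    tx <<- c(tx, -cp[has_p], -cm[has_m])
    if (dirichlet[a]) {
      diag_acc <<- diag_acc + cp + cm      # missing neighbours are walls
    } else {
      diag_acc <<- diag_acc + ifelse(has_p, cp, 0) + ifelse(has_m, cm, 0)
    }
  }
  for (a in 1:3) add_axis(a)
  # mass term, kept separately for the shifted preconditioner
  mass_x <- as.vector(k0^2 * eps_c * Svol)

  keep_mask <- rep(TRUE, length(centre))
  for (a in 1:3) {
    if (dirichlet[a]) {
      idx3 <- list(ii, jj, ll)[[a]]
      keep_mask <- keep_mask & idx3 > 1L & idx3 < d[a]
    }
  }
  interior <- which(keep_mask)
  remap <- rep(NA_integer_, length(centre))
  remap[interior] <- seq_along(interior)
  n_int <- length(interior)

  ti_all <- c(ti, centre)
  tj_all <- c(tj, centre)
  xk_all <- c(tx, diag_acc)
  xm_all <- c(complex(length(tx)), mass_x)
  keep <- !is.na(remap[ti_all]) & !is.na(remap[tj_all])
  agg <- aggregate_triplets(remap[ti_all[keep]], remap[tj_all[keep]],
                            list(K = xk_all[keep], M = xm_all[keep]), n_int)
  A <- new_csc(n_int, agg$p, agg$i, agg$xs[[1]] - agg$xs[[2]])

  # sources at their exact physical position, spread (bi/tri)linearly onto the
  # surrounding unknowns so the location is grid-independent
  b <- complex(n_int)
  src_nodes <- integer(0)
  cellvol <- prod(h)
  axis_weights <- function(a, pos) {
    ia <- min(max(findInterval(pos, co[[a]]), 1L), d[a] - 1L)
    t <- (pos - co[[a]][ia]) / (co[[a]][ia + 1L] - co[[a]][ia])
    t <- min(max(t, 0), 1)
    list(idx = c(ia, ia + 1L), w = c(1 - t, t))
  }
  for (s in seq_len(nrow(problem$sources))) {
    wx <- axis_weights(1L, problem$sources$x[s])
    wy <- axis_weights(2L, problem$sources$y[s])
    amp <- problem$sources$amplitude[s]
    if (line_source_z) {
      for (ax in 1:2) for (ay in 1:2) {
        wxy <- wx$w[ax] * wy$w[ay]
        if (wxy < 1e-12) next
        gn <- lin(rep(wx$idx[ax], d[3]), rep(wy$idx[ay], d[3]), seq_len(d[3]))
        gn <- gn[!is.na(remap[gn])]
        b[remap[gn]] <- b[remap[gn]] -
          1i * w * k$mu0 * amp * wxy / (h[1] * h[2])
        src_nodes <- c(src_nodes, remap[gn])
      }
    } else {
      wz <- axis_weights(3L, problem$sources$z[s])
      for (ax in 1:2) for (ay in 1:2) for (az in 1:2) {
        www <- wx$w[ax] * wy$w[ay] * wz$w[az]
        if (www < 1e-12) next
        gn <- lin(wx$idx[ax], wy$idx[ay], wz$idx[az])
        if (is.na(remap[gn])) stop("source on the Dirichlet boundary")
        b[remap[gn]] <- b[remap[gn]] - 1i * w * k$mu0 * amp * www / cellvol
        src_nodes <- c(src_nodes, remap[gn])
      }
    }
  }

  structure(
    list(A = A, Mx = agg$xs[[2]], b = b, dof = n_int,
         node_dim = d, interior = interior,
         node_coords = co, spacing = map$spacing,
         frequency = problem$frequency, k0 = k0,
         dielectric = map, sources = problem$sources,
         src_nodes = src_nodes, pml = profiles, kind = "fd3d"),
    class = "helmholtz_system"
  )
}
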