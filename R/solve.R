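#' Solve an assembled Helmholtz system
#'
#' Solves the complex sparse system with one of the hand-written Krylov
#' methods (GMRES, FGMRES, BiCGStab) or a direct sparse LU of the equivalent
#' real system. Iterative methods are right-preconditioned with an ILU(0)
#' factorization of a complex-shifted copy of the operator (shift
#' `beta * k0^2 eps` on the mass term; `beta = 0` is plain ILU(0)). On success
#' the relative residual `||Ax - b|| / ||b||` is at or below `tolerance`; on
#' non-convergence an error of class `mwihead_no_convergence` carrying the
#' residual history is raised -- never a silent partial answer.
#'
#' @param system A `helmholtz_system` from [assemble_2d()] or
#'   [assemble_3d_scalar()].
#' @param method `"gmres"`, `"fgmres"`, `"bicgstab"` or `"direct"`.
#' @param tolerance Relative residual tolerance in (0, 1).
#' @param max_iterations Iteration cap for the Krylov methods.
#' @param preconditioner `"ilu0"` or `"none"`.
#' @param shift_beta Complex-shift parameter for the preconditioner.
#' @param restart GMRES restart length.
#' @return A `field_solution`: the complex field on the full node grid (zeros
#'   on the eliminated Dirichlet boundary) plus solver metadata.
#' @export
solve_field <- function(system,
                        method = c("gmres", "fgmres", "bicgstab", "direct"),
                        tolerance = 1e-3, max_iterations = 2000L,
                        preconditioner = c("ilu0", "none"),
                        shift_beta = 0.5, restart = 60L) {
  stopifnot(inherits(system, "helmholtz_system"))
  method <- match.arg(method)
  preconditioner <- match.arg(preconditioner)
  if (tolerance <= 0 || tolerance >= 1) stop("`tolerance` must be in (0, 1)")
  A <- system$A
  b <- system$b
  t0 <- proc.time()[["elapsed"]]

  if (method == "direct") {
    B <- csc_real_equivalent(A)
    z <- Matrix::solve(B, c(Re(b), Im(b)))
    x <- complex(real = z[seq_len(A$n)], imaginary = z[A$n + seq_len(A$n)])
    res <- cnorm(b - csc_matvec(A, x)) / max(cnorm(b), .Machine$double.xmin)
    info <- list(x = x, iterations = 1L, residual = res,
                 history = res, converged = TRUE)
  } else {
    matvec <- function(v) csc_matvec(A, v)
    prec <- identity
    if (preconditioner == "ilu0") {
      Px <- A$x + 1i * shift_beta * system$Mx
      fac <- ilu0_factor(A$p, A$i, Px)
      prec <- function(v) ilu0_solve(A$p, A$i, fac$x, fac$diag, v)
    }
    info <- switch(method,
      gmres = gmres_c(matvec, b, prec, tol = tolerance,
                      maxit = max_iterations, restart = restart),
      fgmres = gmres_c(matvec, b, prec, tol = tolerance,
                       maxit = max_iterations, restart = restart,
                       flexible = TRUE),
      bicgstab = bicgstab_c(matvec, b, prec, tol = tolerance,
                            maxit = max_iterations)
    )
    if (!info$converged) {
      cond <- structure(
        class = c("mwihead_no_convergence", "error", "condition"),
        list(message = sprintf(
               "%s did not reach tolerance %g in %d iterations (residual %.3g)",
               method, tolerance, info$iterations, info$residual),
             call = sys.call(),
             residual_history = info$history,
             residual = info$residual, iterations = info$iterations)
      )
      stop(cond)
    }
  }
  wall <- proc.time()[["elapsed"]] - t0

  E_full <- complex(prod(system$node_dim))
  E_full[system$interior] <- info$x
  E <- array(E_full, dim = system$node_dim)
  structure(
    list(E = E, coords = system$node_coords, spacing = system$spacing,
         frequency = system$frequency, k0 = system$k0,
         dielectric = system$dielectric, sources = system$sources,
         method = method, iterations = info$iterations,
         residual = info$residual, residual_history = info$history,
         dof = system$dof, wall_time = wall, kind = system$kind),
    class = "field_solution"
  )
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> ", paste(dim(x$E), collapse = " x "), " nodes, ",
      x$dof, " DOF; ", x$method, ": ", x$iterations,
      " iterations, residual ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' Solver metadata of a field solution
#'
#' @param x A `field_solution`.
#' @param ... Unused.
#' @return One-row tibble with method, iterations, residual, DOF, wall time.
#' @export
glance.field_solution <- function(x, ...) {
  tibble::tibble(method = x$method, iterations = x$iterations,
                 residual = x$residual, dof = x$dof,
                 wall_time = x$wall_time,
                 frequency = x$frequency)
}

#' Tidy a 2D field solution into a long tibble
#'
#' @param x A `field_solution` with a 2D node grid.
#' @param ... Unused.
#' @return Tibble with node coordinates, `re`, `im` and `enorm`.
#' @export
tidy.field_solution <- function(x, ...) {
  d <- dim(x$E)
  if (length(d) != 2L) stop("tidy() supports 2D field solutions")
  tibble::tibble(
    x = rep(x$coords[[1]], times = d[2]),
    y = rep(x$coords[[2]], each = d[1]),
    re = as.numeric(Re(x$E)),
    im = as.numeric(Im(x$E)),
    enorm = as.numeric(Mod(x$E))
  )
}

#' Plot the |E| map of a 2D field solution
#'
#' @param object A `field_solution`.
#' @param trans Transformation for the fill scale (e.g. `"sqrt"`).
#' @param ... Unused.
#' @return A ggplot object (linear colour scale by default).
#' @export
autoplot.field_solution <- function(object, trans = "identity", ...) {
  df <- tidy.field_solution(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$enorm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "|E| (V/m)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

# bilinear interpolation of a node-grid matrix at physical points (mm)
interp_bilinear <- function(M, coords, px, py) {
  xs <- coords[[1]]; ys <- coords[[2]]
  fx <- findInterval(px, xs, rightmost.closed = TRUE)
  fy <- findInterval(py, ys, rightmost.closed = TRUE)
  fx <- pmin(pmax(fx, 1L), length(xs) - 1L)
  fy <- pmin(pmax(fy, 1L), length(ys) - 1L)
  tx <- (px - xs[fx]) / (xs[fx + 1L] - xs[fx])
  ty <- (py - ys[fy]) / (ys[fy + 1L] - ys[fy])
  v00 <- M[cbind(fx, fy)]
  v10 <- M[cbind(fx + 1L, fy)]
  v01 <- M[cbind(fx, fy + 1L)]
  v11 <- M[cbind(fx + 1L, fy + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Probe |E| of a field solution at physical points
#'
#' Bilinear interpolation of the field-norm map on the node grid (2D).
#'
#' @param field A `field_solution`.
#' @param points Data frame with in-plane coordinates in mm (first two columns
#'   or columns named after the in-plane axes).
#' @return Numeric vector of |E| values (V/m).
#' @export
probe_enorm <- function(field, points) {
  axes <- if (!is.null(field$dielectric$axes)) field$dielectric$axes[1:2] else c("x", "y")
  px <- if (axes[1] %in% names(points)) points[[axes[1]]] else points[[1]]
  py <- if (axes[2] %in% names(points)) points[[axes[2]]] else points[[2]]
  interp_bilinear(Mod(field$E), field$coords, px, py)
}

#' Mesh-convergence study over a refinement ladder
#'
#' Solves the same physical problem on a ladder of meshes (finest last),
#' probes |E| at a fixed point, and reports each model's absolute difference
#' against the finest model. The selected model is the coarsest one whose
#' difference is at or below `tolerance` -- the protocol used to justify a
#' production mesh; the finest model's self-difference is exactly 0. If no
#' model meets the tolerance the finest is selected with a warning.
#'
#' @param problems List of >= 3 [helmholtz_problem()]s ordered coarse to fine.
#' @param probe_point Length-2 (or data frame row) physical probe point (mm).
#' @param tolerance Absolute |E| difference tolerance (V/m).
#' @param method,solver_tolerance,... Passed to [solve_field()]; the default
#'   direct solve isolates discretization error from iteration error.
#' @return A `convergence_report`: tibble with per-model element size, element
#'   count, DOF, probe |E| and difference vs the finest, plus attributes
#'   `selected` (model index) and `tolerance`.
#' @export
mesh_convergence_study <- function(problems, probe_point, tolerance = 1e-3,
                                   method = "direct", solver_tolerance = 1e-8,
                                   ...) {
  if (length(problems) < 3L) stop("need at least 3 mesh models (finest last)")
  k <- physical_constants()
  rows <- vector("list", length(problems))
  for (m in seq_along(problems)) {
    pr <- problems[[m]]
    h_mm <- max(pr$dielectric$spacing)
    lam_min_mm <- 1000 * k$c / pr$frequency / sqrt(max(pr$dielectric$eps_r))
    if (h_mm > lam_min_mm / 5) {
      warning(sprintf(
        "model %d: element size %.3g mm exceeds lambda/5 = %.3g mm in the densest tissue",
        m, h_mm, lam_min_mm / 5))
    }
    sys <- assemble_2d(pr)
    sol <- solve_field(sys, method = method, tolerance = solver_tolerance, ...)
    d <- dim(pr$dielectric$eps_r)
    rows[[m]] <- tibble::tibble(
      model = m, h_mm = h_mm, elements = 2L * prod(d), dof = sol$dof,
      iterations = sol$iterations,
      probe_enorm = probe_enorm(sol, data.frame(x = probe_point[1],
                                                y = probe_point[2]))
    )
  }
  tb <- dplyr::bind_rows(rows)
  tb$abs_diff <- abs(tb$probe_enorm - tb$probe_enorm[nrow(tb)])
  ok <- which(tb$abs_diff <= tolerance)
  ok <- ok[ok < nrow(tb)]
  if (length(ok)) {
    selected <- min(ok)
  } else {
    selected <- nrow(tb)
    warning("no coarser model met the tolerance; selecting the finest model")
  }
  tb$selected <- seq_len(nrow(tb)) == selected
  structure(tb, class = c("convergence_report", class(tb)),
            selected = selected, tolerance = tolerance,
            probe_point = probe_point)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> tolerance ", attr(x, "tolerance"),
      " V/m, selected model ", attr(x, "selected"), "\n", sep = "")
  NextMethod()
}

#' Plot a convergence report
#'
#' @param object A `convergence_report`.
#' @param ... Unused.
#' @return A ggplot of probe |E| difference vs the finest model.
#' @export
autoplot.convergence_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[-nrow(df), ],
                  ggplot2::aes(.data$h_mm, .data$abs_diff)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "tolerance"),
                        linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "element size (mm)",
                  y = "|E| abs. difference vs finest (V/m)") +
    ggplot2::theme_minimal()
}

#' Benchmark iterative solvers on one problem
#'
#' Assembles the problem once and solves it with each requested method,
#' reporting iterations, wall time and the probe |E|. All converged methods
#' must describe the same field; the probe column makes that auditable (wall
#' times are reported, never asserted). Failing methods are flagged, the
#' comparison proceeds with the survivors.
#'
#' @param problem A [helmholtz_problem()] (2D).
#' @param methods At least two of `"gmres"`, `"fgmres"`, `"bicgstab"`.
#' @param tolerance,max_iterations,preconditioner,... Passed to
#'   [solve_field()].
#' @param probe_point Physical probe point (mm); defaults to the domain origin.
#' @return A tibble sorted by wall time (failed rows last) with columns
#'   `method`, `converged`, `iterations`, `wall_time`, `residual`,
#'   `probe_enorm`, `dof`.
#' @export
solver_benchmark <- function(problem, methods = c("gmres", "fgmres", "bicgstab"),
                             tolerance = 1e-3, max_iterations = 2000L,
                             preconditioner = "ilu0",
                             probe_point = c(0, 0), ...) {
  if (length(methods) < 2L) stop("nothing to compare: supply >= 2 methods")
  sys <- assemble_2d(problem)
  rows <- lapply(methods, function(m) {
    t0 <- proc.time()[["elapsed"]]
    sol <- tryCatch(
      solve_field(sys, method = m, tolerance = tolerance,
                  max_iterations = max_iterations,
                  preconditioner = preconditioner, ...),
      mwihead_no_convergence = function(e) e
    )
    wall <- proc.time()[["elapsed"]] - t0
    if (inherits(sol, "field_solution")) {
      tibble::tibble(method = m, converged = TRUE,
                     iterations = sol$iterations, wall_time = wall,
                     residual = sol$residual,
                     probe_enorm = probe_enorm(sol, data.frame(
                       x = probe_point[1], y = probe_point[2])),
                     dof = sol$dof)
    } else {
      tibble::tibble(method = m, converged = FALSE,
                     iterations = sol$iterations, wall_time = wall,
                     residual = sol$residual, probe_enorm = NA_real_,
                     dof = sys$dof)
    }
  })
  tb <- dplyr::bind_rows(rows)
  dplyr::arrange(tb, dplyr::desc(.data$converged), .data$wall_time)
}
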