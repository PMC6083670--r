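# independent dense assembly oracle: coordinate-geometry gradients per
# triangle and edge-midpoint quadrature for the mass term
dense_assembly_oracle <- function(map, frequency, pml) {
  k <- physical_constants()
  w <- 2 * pi * frequency
  k0 <- w / k$c
  d <- dim(map$eps_r)
  nodes <- mwihead:::node_grid_coords(map)
  prof <- make_pml(nodes, pml, frequency)
  cx <- (nodes[[1]][-1] + nodes[[1]][-(d[1] + 1)]) / 2
  cy <- (nodes[[2]][-1] + nodes[[2]][-(d[2] + 1)]) / 2
  eps <- map_complex_eps(map)
  N <- (d[1] + 1) * (d[2] + 1)
  A <- matrix(0i, N, N)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sx <- prof[[1]]$s(cx[i]); sy <- prof[[2]]$s(cy[j])
    ax <- sy / sx; ay <- sx / sy
    q <- k0^2 * eps[i, j] * sx * sy
    x0 <- nodes[[1]][i] / 1000; x1 <- nodes[[1]][i + 1] / 1000
    y0 <- nodes[[2]][j] / 1000; y1 <- nodes[[2]][j + 1] / 1000
    n00 <- i + (j - 1) * (d[1] + 1); n10 <- n00 + 1
    n01 <- n00 + d[1] + 1; n11 <- n01 + 1
    tris <- list(list(n = c(n00, n10, n11),
                      p = rbind(c(x0, y0), c(x1, y0), c(x1, y1))),
                 list(n = c(n00, n11, n01),
                      p = rbind(c(x0, y0), c(x1, y1), c(x0, y1))))
    for (tr in tris) {
      V <- cbind(1, tr$p)
      C <- solve(V)                       # rows: 1, x, y coefficients
      area <- abs(det(V)) / 2
      gb <- C[2, ]; gc <- C[3, ]
      Ke <- area * (ax * outer(gb, gb) + ay * outer(gc, gc))
      mid <- (tr$p[c(1, 2, 3), ] + tr$p[c(2, 3, 1), ]) / 2
      phi <- V %*% C                      # identity; evaluate at midpoints:
      phim <- cbind(1, mid) %*% C         # 3 x 3 basis values at midpoints
      Me <- area / 3 * t(phim) %*% phim
      A[tr$n, tr$n] <- A[tr$n, tr$n] + Ke - q * Me
    }
  }
  bx <- rep(seq_len(d[1] + 1), times = d[2] + 1)
  by <- rep(seq_len(d[2] + 1), each = d[1] + 1)
  interior <- which(bx > 1 & bx < d[1] + 1 & by > 1 & by < d[2] + 1)
  A[interior, interior]
}

test_that("assembly matches a hand-assembled two-triangle oracle", {
  set.seed(5)
  n <- 10
  map <- raw_map_2d(matrix(stats::runif(n^2, 1, 50), n),
                    matrix(stats::runif(n^2, 0, 2), n), h = 12)
  pr <- helmholtz_problem(map, tibble::tibble(x = 0, y = 0, amplitude = 1 + 0i),
                          pml = pml_spec(4))
  sys <- assemble_2d(pr)
  expect_equal(csc_to_dense(sys$A),
               dense_assembly_oracle(map, map$frequency, pml_spec(4)),
               tolerance = 1e-12)
  # load: bilinear weights sum to the full -j w mu0 I
  k <- physical_constants()
  expect_equal(sum(sys$b), -1i * 2 * pi * 1e9 * k$mu0, tolerance = 1e-12)
})

test_that("the system matrix is complex symmetric on a random lossy map", {
  set.seed(9)
  n <- 14
  map <- raw_map_2d(matrix(stats::runif(n^2, 1, 60), n),
                    matrix(stats::runif(n^2, 0, 2.5), n), h = 10)
  sys <- assemble_2d(helmholtz_problem(
    map, tibble::tibble(x = 0, y = 0, amplitude = 1 + 0i), pml = pml_spec(4)))
  Ad <- csc_to_dense(sys$A)
  expect_lt(max(Mod(Ad - t(Ad))) / max(Mod(Ad)), 1e-12)
  expect_gt(max(Mod(Ad - Conj(t(Ad)))), 0)   # non-Hermitian (lossy)
})

test_that("no source means an identically zero field", {
  sl <- air_slice(16, 5)
  map <- build_dielectric_map(sl, frequency = 1e9)
  sys <- assemble_2d(helmholtz_problem(
    map, tibble::tibble(x = 0, y = 0, amplitude = 0 + 0i), pml = pml_spec(4)))
  sol <- solve_field(sys, "gmres", tolerance = 1e-6)
  expect_true(all(sol$E == 0))
})

test_that("sources inside the PML or empty maps are rejected", {
  sl <- air_slice(16, 5)
  map <- build_dielectric_map(sl, frequency = 1e9)
  expect_error(assemble_2d(helmholtz_problem(
    map, tibble::tibble(x = 38, y = 0, amplitude = 1 + 0i), pml = pml_spec(4))),
    "PML")
  expect_error(helmholtz_problem(map, tibble::tibble(x = 0, amplitude = 1)),
               "columns")
})

test_that("swapping source and receiver is reciprocal in a fixed medium", {
  cfg <- coarse_config()
  scene <- setup_scene(cfg)
  healthy <- build_dielectric_map(scene$slice)
  p1 <- c(95, 10); p2 <- c(-15, -95)
  solve_at <- function(p) {
    sys <- assemble_2d(helmholtz_problem(
      healthy, tibble::tibble(x = p[1], y = p[2], amplitude = 1 + 0i),
      pml = scene$pml))
    solve_field(sys, "direct")
  }
  e12 <- probe_complex(solve_at(p1), p2[1], p2[2])
  e21 <- probe_complex(solve_at(p2), p1[1], p1[2])
  expect_lt(Mod(e12 - e21) / Mod(e12), 1e-6)
})

test_that("absorption never amplifies: head fields below free-space fields", {
  cfg <- coarse_config()
  scene <- setup_scene(cfg)
  healthy <- build_dielectric_map(scene$slice)
  airmap <- healthy
  airmap$eps_r[] <- 1; airmap$sigma[] <- 0
  src <- mwihead:::scene_sources(scene, 7L)
  sol_h <- solve_field(assemble_2d(helmholtz_problem(healthy, src,
                                                     pml = scene$pml)), "direct")
  sol_a <- solve_field(assemble_2d(helmholtz_problem(airmap, src,
                                                     pml = scene$pml)), "direct")
  mask <- mwihead:::node_head_mask(healthy$labels)
  expect_lt(mean(Mod(sol_h$E)[mask]), mean(Mod(sol_a$E)[mask]))
})

test_that("manufactured-solution error shrinks about 4x per mesh halving", {
  k <- physical_constants()
  f <- 1e9
  k0 <- 2 * pi * f / k$c
  L <- 3 * pi / k0 * 1000       # three half-wavelengths, non-resonant
  errs <- sapply(c(24, 48, 96), function(ncell) {
    h <- L / ncell
    sl <- air_slice(ncell, h)
    map <- build_dielectric_map(sl, frequency = f)
    sys <- assemble_2d(helmholtz_problem(
      map, tibble::tibble(x = 0, y = 0, amplitude = 0i),
      pml = pml_spec(4, 3, 1 - 1e-9)))     # inert layer: pure Dirichlet box
    xs <- sys$node_coords[[1]] - min(sys$node_coords[[1]])
    ys <- sys$node_coords[[2]] - min(sys$node_coords[[2]])
    Ex <- outer(sin(k0 * xs / 1000), sin(k0 * ys / 1000))
    Mmat <- mwihead:::new_csc(sys$A$n, sys$A$p, sys$A$i, sys$Mx)
    sys$b <- mwihead:::csc_matvec(Mmat, as.vector(Ex)[sys$interior])
    sol <- solve_field(sys, "direct")
    sqrt(sum(Mod(sol$E - Ex)^2) / sum(Mod(Ex)^2))
  })
  expect_gt(errs[1] / errs[2], 4 / 1.3)
  expect_lt(errs[1] / errs[2], 4 * 1.3)
  expect_gt(errs[2] / errs[3], 4 / 1.3)
  expect_lt(errs[2] / errs[3], 4 * 1.3)
})

test_that("a z-invariant slab solved in 3D matches the 2D solve", {
  f <- 2e9; h <- 3; n <- 60
  lab2 <- matrix(1L, n, n)
  cx <- mwihead:::axis_coords(n, h, 0)
  lab2[outer(abs(cx) < 35, abs(cx) < 45, "&")] <- 4L    # fat block
  vocab <- c(`air/free space` = 1L, fat = 4L)
  sl2 <- air_slice(n, h)
  sl2$labels <- lab2; sl2$label_vocab <- vocab
  map2 <- build_dielectric_map(sl2, frequency = f)
  src <- tibble::tibble(x = -63, y = 0, z = 0, amplitude = 1 + 0i)
  sol2 <- solve_field(assemble_2d(helmholtz_problem(map2, src,
                                                    pml = pml_spec(6))),
                      "direct")
  nz <- 5
  ph3 <- voxel_phantom(array(rep(lab2, nz), c(n, n, nz)), c(h, h, h),
                       label_vocab = vocab)
  map3 <- build_dielectric_map(ph3, frequency = f)
  sys3 <- assemble_3d_scalar(helmholtz_problem(map3, src, pml = pml_spec(6),
                                               pml_axes = c("x", "y")),
                             line_source_z = TRUE)
  sol3 <- solve_field(sys3, "gmres", tolerance = 1e-6, max_iterations = 4000)
  # z-invariance across planes
  expect_lt(max(abs(Mod(sol3$E[, , 2]) - Mod(sol3$E[, , 4]))), 1e-4)
  # mid-plane agreement with the 2D solution away from the PML
  mid <- sol3$E[, , 3]
  pts <- expand.grid(x = cx, y = cx)
  E2 <- matrix(probe_complex(sol2, pts$x, pts$y), n, n)
  keep <- outer(abs(cx) < max(cx) - 8 * h, abs(cx) < max(cx) - 8 * h, "&")
  rel <- sqrt(sum(Mod(mid - E2)[keep]^2) / sum(Mod(E2)[keep]^2))
  expect_lt(rel, 0.05)
})

test_that("a 3D free-space point source decays monotonically with radius", {
  f <- 3e9; h <- 5; n <- 29
  ph <- voxel_phantom(array(1L, c(n, n, n)), c(h, h, h),
                      label_vocab = c(`air/free space` = 1L))
  map <- build_dielectric_map(ph, frequency = f)
  src <- tibble::tibble(x = 0, y = 0, z = 0, amplitude = 1 + 0i)
  sys <- assemble_3d_scalar(helmholtz_problem(map, src, pml = pml_spec(5)))
  sol <- solve_field(sys, "gmres", tolerance = 1e-8, max_iterations = 4000)
  ic <- (n + 1) / 2
  ray <- Mod(sol$E[(ic + 2):(n - 6), ic, ic])    # 2 cells off the source
  expect_true(all(diff(ray) < 0))
})

test_that("the DOF cap rejects oversized 3D systems with advice", {
  ph <- voxel_phantom(array(1L, c(150, 150, 100)), c(2.2, 2.2, 2.2),
                      label_vocab = c(`air/free space` = 1L))
  map <- build_dielectric_map(ph, frequency = 1e9)
  pr <- helmholtz_problem(map, tibble::tibble(x = 0, y = 0, z = 0,
                                              amplitude = 1 + 0i),
                          pml = pml_spec(8))
  expect_error(assemble_3d_scalar(pr), "coarsen")
  # the same grid passes under a raised cap's arithmetic
  expect_error(assemble_3d_scalar(pr, dof_cap = 1e6), "cap 1e\\+06")
})
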