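# a synthetic field_solution on an n x n node grid over the given map
fake_field <- function(E, map) {
  d <- dim(map$eps_r)
  structure(
    list(E = E, coords = mwihead:::node_grid_coords(map),
         spacing = map$spacing, frequency = map$frequency,
         k0 = 2 * pi * map$frequency / 299792458,
         dielectric = map, sources = NULL, method = "direct",
         iterations = 1L, residual = 0, residual_history = 0,
         dof = prod(d + 1L), wall_time = 0, kind = "fem2d"),
    class = "field_solution"
  )
}

test_that("enorm is the pointwise magnitude and phase-invariant", {
  map <- raw_map_2d(matrix(1, 4, 4), matrix(0, 4, 4), h = 5)
  E <- matrix(0i, 5, 5)
  E[2, 3] <- 3 + 4i
  f <- fake_field(E, map)
  expect_identical(enorm(f)[2, 3], 5)
  expect_true(all(enorm(fake_field(matrix(0i, 5, 5), map)) == 0))
  g <- fake_field(E * exp(1i * 1.234), map)
  expect_equal(enorm(g), enorm(f), tolerance = 1e-12)
})

test_that("probe points sit one radius from the centre along the axes", {
  spec <- stroke_spec("haemorrhagic", centre = c(0, -70, 26.6), radius = 10)
  pts <- probe_points(spec)
  expect_identical(pts$point,
                   c("left", "front", "bottom", "centre", "top", "back", "right"))
  front <- pts[pts$point == "front", ]
  expect_equal(c(front$x, front$y, front$z), c(0, -80, 26.6))
  ctr <- unlist(pts[pts$point == "centre", c("x", "y", "z")])
  expect_equal(unname(ctr), spec$centre)
  left <- unlist(pts[pts$point == "left", c("x", "y", "z")])
  right <- unlist(pts[pts$point == "right", c("x", "y", "z")])
  expect_equal(unname(left + right), 2 * spec$centre)   # mirror images
  d <- as.matrix(pts[pts$point != "centre", c("x", "y", "z")])
  expect_equal(unname(sqrt(rowSums(sweep(d, 2, spec$centre)^2))),
               rep(10, 6))
  expect_error(stroke_spec("haemorrhagic", c(0, 0, 0), radius = 0), "radius")
})

test_that("identical fields give a symmetric, zero, 'no contrast' report", {
  ph <- generate_layered_head(spacing = 5)
  sl <- extract_slice(ph, "z", slice_index_at(ph, "z", 26.6))
  map <- build_dielectric_map(sl)
  set.seed(2)
  d <- dim(map$eps_r) + 1L
  E <- matrix(complex(real = stats::rnorm(prod(d)),
                      imaginary = stats::rnorm(prod(d))), d[1], d[2])
  spec <- stroke_spec("ischaemic", c(0, 0, 26.6), 10)
  f <- fake_field(E, map)
  rep0 <- diff_analysis(f, f, spec)
  expect_true(all(rep0$D == 0))
  expect_identical(rep0$note, "no contrast")
  expect_true(is.na(rep0$peak$x))

  # D is symmetric in its two arguments
  g <- fake_field(E + 0.1, map)
  r1 <- diff_analysis(f, g, spec)
  r2 <- diff_analysis(g, f, spec)
  expect_identical(r1$D, r2$D)
  expect_true(all(r1$D >= 0))
  # probe diffs equal D sampled at the probe points
  expect_equal(r1$probe_table$abs_diff,
               abs(r1$probe_table$enorm_normal - r1$probe_table$enorm_stroke))
})

test_that("mesh or frequency mismatches are rejected", {
  map5 <- raw_map_2d(matrix(1, 6, 6), matrix(0, 6, 6), h = 5)
  map4 <- raw_map_2d(matrix(1, 7, 7), matrix(0, 7, 7), h = 5)
  spec <- stroke_spec("ischaemic", c(0, 0, 0), 10)
  f5 <- fake_field(matrix(1 + 0i, 7, 7), map5)
  f4 <- fake_field(matrix(1 + 0i, 8, 8), map4)
  expect_error(diff_analysis(f5, f4, spec), "mesh mismatch")
  map5b <- map5; map5b$frequency <- 2e9
  g5 <- fake_field(matrix(1 + 0i, 7, 7), map5b)
  expect_error(diff_analysis(f5, g5, spec), "frequency")
})

test_that("differential localization finds a known stroke on the coarse head", {
  cfg <- coarse_config()
  scene <- setup_scene(cfg)
  healthy <- build_dielectric_map(scene$slice)
  spec <- stroke_spec("haemorrhagic", centre = c(22, 0, 26.6), radius = 10)
  dmap <- build_dielectric_map(scene$slice, stroke = spec)
  normal <- solve_field(assemble_2d(mwihead:::scene_problem(scene, healthy, 1L)),
                        "direct")
  stroked <- solve_field(assemble_2d(mwihead:::scene_problem(scene, dmap, 1L)),
                         "direct")
  rep <- diff_analysis(normal, stroked, spec)
  expect_lte(rep$loc_error, spec$radius + 2 * cfg$spacing)
  expect_gt(rep$peak$value, 0)
  g <- glance(rep)
  expect_identical(g$kind, "haemorrhagic")
  expect_equal(g$loc_error_mm, rep$loc_error)
})

test_that("contrast comparison reports winners and ties without error", {
  map <- raw_map_2d(matrix(37.9, 30, 30), matrix(0.75, 30, 30), h = 5)
  spec <- stroke_spec("haemorrhagic", c(0, 0, 0), 10)
  set.seed(4)
  d <- dim(map$eps_r) + 1L
  E0 <- matrix(complex(real = stats::rnorm(prod(d)),
                       imaginary = stats::rnorm(prod(d))), d[1], d[2])
  f0 <- fake_field(E0, map)
  fh <- fake_field(E0 * 1.3, map)
  fi <- fake_field(E0 * 1.1, map)
  rh <- diff_analysis(f0, fh, spec)
  ri <- diff_analysis(f0, fi, spec)
  out <- contrast_compare(rh, ri, region_label = "white matter (WM)")
  expect_identical(out$larger_peak, "haemorrhagic")
  expect_identical(out$region, "white matter (WM)")
  tie <- contrast_compare(rh, rh, region_label = "x")
  expect_identical(tie$larger_peak, "tie")
  spec2 <- stroke_spec("ischaemic", c(5, 0, 0), 10)
  ri2 <- diff_analysis(f0, fi, spec2)
  expect_error(contrast_compare(rh, ri2), "geometry mismatch")
})

test_that("increasing dielectric contrast never shrinks the peak difference", {
  cfg <- coarse_config(spacing = 5)
  scene <- setup_scene(cfg)
  healthy <- build_dielectric_map(scene$slice)
  normal <- solve_field(assemble_2d(mwihead:::scene_problem(scene, healthy, 1L)),
                        "direct")
  wm <- c(eps_r = 37.8741, sigma = 0.7477)
  peaks <- sapply(c(0.5, 1, 2), function(scale) {
    ov <- wm + scale * (c(61.0650, 1.5829) - wm)
    spec <- stroke_spec("haemorrhagic", c(22, 0, 26.6), 10, override = ov)
    dmap <- build_dielectric_map(scene$slice, stroke = spec)
    sol <- solve_field(assemble_2d(mwihead:::scene_problem(scene, dmap, 1L)),
                       "direct")
    diff_analysis(normal, sol, spec)$peak$value
  })
  expect_true(all(diff(peaks) >= 0))
})
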