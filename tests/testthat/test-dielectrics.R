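test_that("a pole-free model returns eps_inf exactly and inverts cleanly", {
  p <- dispersion_params("debye4", eps_inf = 5, deps = rep(0, 4),
                         tau = rep(1e-12, 4))
  expect_identical(eval_dispersion(p, c(1e8, 1e9, 3e9)), rep(5 + 0i, 3))
  # split/compose round trip
  eps <- complex_permittivity(37.8741, 0.7477, 1e9)
  sp <- split_complex(eps, 1e9)
  expect_equal(sp$eps_r, 37.8741, tolerance = 1e-10)
  expect_equal(sp$sigma, 0.7477, tolerance = 1e-10)
  # free space and purely real permittivities
  expect_equal(split_complex(1 + 0i, 1e9), list(eps_r = 1, sigma = 0))
  expect_equal(split_complex(4 + 0i, 2e9)$sigma, 0)
})

test_that("parameter invariants are enforced", {
  expect_error(dispersion_params("debye4", 0.5, rep(1, 4), rep(1e-9, 4)),
               "eps_inf")
  expect_error(dispersion_params("debye4", 4, rep(1, 4), c(-1e-9, rep(1e-9, 3))),
               "tau")
  expect_error(dispersion_params("colecole4", 4, rep(1, 4), rep(1e-9, 4),
                                 alpha = c(1, 0, 0, 0)), "alpha")
  expect_error(dispersion_params("debye4", 4, rep(1, 4), rep(1e-9, 4),
                                 alpha = c(0.1, 0, 0, 0)), "debye4")
  p <- dispersion_params("debye4", 4, rep(1, 4), rep(1e-9, 4))
  expect_error(eval_dispersion(p, -1e9), "frequency")
})

test_that("Cole-Cole with zero broadening reduces to Debye at machine precision", {
  set.seed(42)
  base <- list(eps_inf = 4, deps = c(40, 3, 25, 200),
               tau = c(8.8e-12, 1e-9, 1.5e-7, 1e-5), sigma_static = 0.6)
  pd <- dispersion_params("debye4", base$eps_inf, base$deps, base$tau,
                          sigma_static = base$sigma_static)
  pc <- dispersion_params("colecole4", base$eps_inf, base$deps, base$tau,
                          alpha = rep(0, 4), sigma_static = base$sigma_static)
  f <- 10^stats::runif(100, 8, 9.5)
  expect_equal(eval_dispersion(pc, f), eval_dispersion(pd, f),
               tolerance = 1e-14)
})

test_that("shipped parameters reproduce the published 1 GHz tissue table", {
  params <- head_dispersion_params()
  ref <- reference_tissue_table()
  expect_setequal(names(params), ref$tissue)
  sw <- frequency_sweep(params, 1e9)
  m <- merge(sw, ref, by = "tissue")
  expect_true(all(abs(m$eps_r.x - m$eps_r.y) < 0.01))
  expect_true(all(abs(m$sigma.x - m$sigma.y) < 0.01))
  expect_identical(nrow(sw), 21L)
})

test_that("dispersion models are passive and relax toward eps_inf", {
  params <- head_dispersion_params()
  f <- seq(1e8, 3e9, length.out = 30)
  sw <- frequency_sweep(params, f)
  expect_true(all(sw$sigma >= 0))
  for (p in params) {
    if (p$model_tag == "debye4") {
      er <- Re(eval_dispersion(p, f))
      expect_true(all(diff(er) <= 1e-12))   # monotone non-increasing
    }
    e_hi <- Re(eval_dispersion(p, 1e15))
    expect_lt(abs(e_hi - p$eps_inf), 1e-3 * p$eps_inf)
  }
})

test_that("frequency sweeps deduplicate, warn off-band and reject empties", {
  params <- head_dispersion_params()[c("fat", "stomach")]
  sw <- frequency_sweep(params, c(1e9, 1e9, 2e9))
  expect_identical(sw$frequency[sw$tissue == "fat"], c(1e9, 2e9))
  expect_warning(frequency_sweep(params["fat"], 5e9), "validity band")
  expect_error(frequency_sweep(params, numeric(0)), "non-empty")
})

test_that("dielectric maps are piecewise constant with stroke overrides", {
  # all-air slice: free space everywhere
  sl <- air_slice(12, 5)
  m <- build_dielectric_map(sl, frequency = 1e9)
  expect_true(all(m$eps_r == 1) && all(m$sigma == 0))

  ph <- generate_layered_head(spacing = 4)
  zi <- slice_index_at(ph, "z", 26.6)
  sl <- extract_slice(ph, "z", zi)
  healthy <- build_dielectric_map(sl, frequency = 1e9)
  # the normal-brain control equals the healthy map everywhere
  none <- build_dielectric_map(sl, frequency = 1e9,
                               stroke = stroke_spec("none", c(0, 0, 26.6), 10))
  expect_identical(none$eps_r, healthy$eps_r)
  expect_identical(none$sigma, healthy$sigma)

  # ischaemic stroke differs only inside the sphere, with (30, 0.5)
  isch <- build_dielectric_map(sl, frequency = 1e9,
                               stroke = stroke_spec("ischaemic", c(0, 0, 26.6), 10))
  changed <- isch$eps_r != healthy$eps_r | isch$sigma != healthy$sigma
  expect_true(any(changed))
  expect_true(all(isch$eps_r[changed] == 30))
  expect_true(all(isch$sigma[changed] == 0.5))
  co <- slice_coords(sl)
  d2 <- outer(co$x^2, co$y^2, "+") + (sl$fixed_coord - 26.6)^2
  expect_true(all(d2[changed] <= 100 + 1e-9))

  # haemorrhagic default override carries the printed bleeding values
  ph_h <- insert_stroke(ph, stroke_spec("haemorrhagic", c(0, 0, 26.6), 10))
  mh <- build_dielectric_map(extract_slice(ph_h, "z", zi), frequency = 1e9)
  hit <- extract_slice(ph_h, "z", zi)$labels == 22L
  expect_true(all(mh$eps_r[hit] == 61.0650))
  expect_true(all(mh$sigma[hit] == 1.5829))
})

test_that("missing parameter sets are reported by tissue", {
  sl <- air_slice(10, 5)
  sl$labels[5, 5] <- 9L   # blood, absent from the truncated parameter list
  expect_error(build_dielectric_map(sl, head_dispersion_params()[c("air/free space")]),
               "blood")
})

test_that("the complex map is consistent with (eps_r, sigma) at the frequency", {
  ph <- generate_layered_head(spacing = 6)
  m <- build_dielectric_map(extract_slice(ph, "z", 11), frequency = 1e9)
  ec <- map_complex_eps(m)
  sp <- split_complex(ec, m$frequency)
  expect_equal(max(abs(sp$eps_r - m$eps_r)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sp$sigma - m$sigma)), 0, tolerance = 1e-12)
})
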