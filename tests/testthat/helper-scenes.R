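# shared fixtures, all generated in code

# an all-air 2D slice of ncell x ncell cells with spacing h (mm)
air_slice <- function(ncell, h) {
  ph <- generate_layered_head(list(none = c(0, 0, 0)), spacing = c(h, h, h),
                              grid_dims = c(ncell, ncell, 1L),
                              shell_ids = 2L)
  extract_slice(ph, "z", 1L)
}

# a coarse full scene for fast solver tests
coarse_config <- function(spacing = 4, ...) {
  run_config(spacing = spacing, ...)
}

# the published per-tissue (eps_r, sigma) values at 1 GHz
reference_tissue_table <- function() {
  tibble::tribble(
    ~tissue, ~eps_r, ~sigma,
    "air/free space", 1, 0,
    "skin (dry)", 39.6666, 0.7062,
    "skin (wet)", 47.7684, 0.9314,
    "fat", 4.602, 0.0535,
    "bone, cortical", 12.6348, 0.1831,
    "bone, cancellous", 18.7217, 0.328,
    "white matter (WM)", 37.8741, 0.7477,
    "grey matter (GM)", 49.7739, 1.0916,
    "blood", 55.5956, 1.8885,
    "cerebrospinal fluid (CSF)", 68.1756, 2.4603,
    "dura", 48.0121, 1.0189,
    "bone marrow", 5.1292, 0.0584,
    "cerebellum", 49.4544, 1.0968,
    "spinal cord (nerve)", 33.1778, 0.6322,
    "eye tissue (sclera)", 54.6089, 1.2415,
    "cartilage", 40.2931, 0.8736,
    "muscle, parallel", 60.3305, 1.2905,
    "stomach", 64.7973, 1.2316,
    "tongue", 55.017, 0.9751,
    "trachea", 41.7785, 0.8023,
    "eye lens (nucleus)", 35.6667, 0.5118
  )
}

# complex bilinear probe of a 2D field solution at one physical point
probe_complex <- function(sol, x, y) {
  mwihead:::interp_bilinear(Re(sol$E), sol$coords, x, y) +
    1i * mwihead:::interp_bilinear(Im(sol$E), sol$coords, x, y)
}

# dense complex matrix from the internal CSC container
csc_to_dense <- function(A) {
  M <- matrix(0i, A$n, A$n)
  j <- rep(seq_len(A$n), diff(A$p))
  M[cbind(A$i + 1L, j)] <- A$x
  M
}

# a dielectric_map built directly from (eps_r, sigma) matrices
raw_map_2d <- function(eps_r, sigma, h, frequency = 1e9,
                       labels = NULL) {
  if (is.null(labels)) labels <- matrix(7L, nrow(eps_r), ncol(eps_r))
  structure(
    list(eps_r = eps_r, sigma = sigma, frequency = frequency,
         spacing = c(h, h), origin = c(0, 0), labels = labels,
         axes = c("x", "y")),
    class = "dielectric_map"
  )
}
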