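test_that("degenerate and default layered heads label voxels correctly", {
  # all semi-axes zero: an empty head, every voxel is air
  ph0 <- generate_layered_head(list(none = c(0, 0, 0)), spacing = 2,
                               grid_dims = c(9, 9, 9), shell_ids = 2L)
  expect_true(all(ph0$labels == 1L))

  # default 7-layer head at 2 mm: exactly 8 distinct labels (7 tissues + air)
  ph <- generate_layered_head(spacing = 4)
  expect_setequal(unique(as.integer(ph$labels)), c(1L, 2L, 4L, 5L, 7L, 8L,
                                                   10L, 11L))
})

test_that("spherical shell voxel count matches a brute-force centre scan", {
  r <- 50
  ph <- generate_layered_head(list(ball = c(r, r, r)), spacing = 1,
                              shell_ids = 7L)
  co <- phantom_coords(ph)
  # independent brute force over the same voxel centres
  inside <- outer(outer(co$x^2, co$y^2, "+"), co$z^2, "+") <= r^2
  expect_identical(sum(ph$labels == 7L), sum(inside))
  expect_gt(sum(inside), 0)
})

test_that("non-nested shells are rejected naming the offending pair", {
  expect_error(
    generate_layered_head(list(inner = c(50, 50, 50), outer = c(60, 60, 60)),
                          spacing = 4, shell_ids = c(2L, 4L)),
    "not strictly nested.*outer.*inner"
  )
})

test_that("a grid too small for the outer shell warns and clips", {
  expect_warning(
    generate_layered_head(list(ball = c(50, 50, 50)), spacing = 2,
                          grid_dims = c(11, 11, 11), shell_ids = 7L),
    "clipped"
  )
})

test_that("origin-centred heads are mirror-symmetric about the axis planes", {
  ph <- generate_layered_head(spacing = 5)
  lab <- ph$labels
  d <- dim(lab)
  expect_identical(lab, lab[d[1]:1, , ])
  expect_identical(lab, lab[, d[2]:1, ])
  expect_identical(lab, lab[, , d[3]:1])
})

test_that("raw uint8 phantom files round-trip bit-exactly", {
  set.seed(11)
  labels <- array(sample(0:255, 8^3, replace = TRUE), c(8, 8, 8))
  ph <- voxel_phantom(labels, c(1.1, 1.1, 1.4))
  path <- tempfile(fileext = ".dat")
  write_voxel_phantom(ph, path)
  back <- read_voxel_phantom(path, dims = c(8, 8, 8), spacing = c(1.1, 1.1, 1.4))
  expect_identical(back$labels, ph$labels)
  expect_identical(back$spacing, ph$spacing)
})

test_that("reader enforces the exact byte count", {
  # a full-size 256 x 256 x 128 file is accepted
  path <- tempfile(fileext = ".dat")
  writeBin(as.raw(rep(1L, 256 * 256 * 128)), path)
  ph <- read_voxel_phantom(path, dims = c(256, 256, 128),
                           spacing = c(1.1, 1.1, 1.4))
  expect_identical(dim(ph$labels), c(256L, 256L, 128L))

  # truncation by one byte is a size-mismatch error
  writeBin(as.raw(rep(1L, 256 * 256 * 128 - 1)), path)
  expect_error(read_voxel_phantom(path, dims = c(256, 256, 128),
                                  spacing = c(1.1, 1.1, 1.4)),
               "size mismatch")
})

test_that("tissue mapping conserves voxel counts per fibre", {
  tab <- read_tissue_map()
  expect_identical(sum(tab$model_tag == "debye4"), 56L)
  expect_identical(sum(tab$model_tag == "colecole4"), 4L)
  expect_identical(sort(unique(tab$canonical_id)), 1:21)

  set.seed(7)
  labels <- array(sample(tab$source_id, 20^3, replace = TRUE), c(20, 20, 20))
  ph <- voxel_phantom(labels, c(2, 2, 2))
  mapped <- map_tissues(ph, tab)
  expect_true(all(mapped$labels %in% 1:21))
  # per-fibre conservation, checked by independent histogram arithmetic
  src_counts <- table(factor(labels, levels = tab$source_id))
  for (cid in unique(tab$canonical_id)) {
    srcs <- tab$source_id[tab$canonical_id == cid]
    expect_identical(sum(mapped$labels == cid),
                     as.integer(sum(src_counts[as.character(srcs)])))
  }
  # identity mapping on an already-canonical phantom
  canon <- voxel_phantom(array(sample(1:21, 1000, TRUE), c(10, 10, 10)),
                         c(2, 2, 2))
  expect_identical(map_tissues(canon, tab)$labels, canon$labels)
})

test_that("unmapped source labels raise an error listing the IDs", {
  ph <- voxel_phantom(array(c(1L, 99L), c(2, 1, 1)), c(1, 1, 1))
  expect_error(map_tissues(ph, read_tissue_map()), "99")
})

test_that("stroke insertion relabels exactly the tissue voxels in the sphere", {
  # sphere fully inside homogeneous white matter on a 1 mm grid
  ph <- voxel_phantom(array(7L, c(31, 31, 31)), c(1, 1, 1))
  spec <- stroke_spec("haemorrhagic", centre = c(0, 0, 0), radius = 10)
  out <- insert_stroke(ph, spec)
  # independent lattice count of integer offsets within the radius
  g <- -15:15
  brute <- sum(outer(outer(g^2, g^2, "+"), g^2, "+") <= 100)
  expect_identical(sum(out$labels == 22L), brute)
  expect_true(abs(brute - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3) < 0.01)
  # idempotence and untouched remainder
  expect_identical(insert_stroke(out, spec)$labels, out$labels)
  expect_true(all(out$labels[out$labels != 22L] == 7L))
})

test_that("stroke controls, air protection and the printed centres behave", {
  ph <- generate_layered_head(spacing = 4)
  # kind = none is the unchanged control
  expect_identical(insert_stroke(ph, stroke_spec("none"))$labels, ph$labels)
  # the three canonical stroke centres are accepted
  for (ctr in list(c(0, -70, 26.6), c(0, 0, 26.6), c(22, 0, 26.6))) {
    out <- insert_stroke(ph, stroke_spec("ischaemic", ctr, 10))
    expect_gt(sum(out$labels == 23L), 0)
  }
  # air is never overwritten
  out <- insert_stroke(ph, stroke_spec("ischaemic", c(0, -105, 0), 10))
  co <- phantom_coords(ph)
  hit <- mwihead:::voxel_dist2(ph, c(0, -105, 0)) <= 100
  expect_true(all(out$labels[hit & ph$labels == 1L] == 1L))
  # entirely outside the head: rejected
  expect_error(insert_stroke(ph, stroke_spec("ischaemic", c(0, -150, 0), 10)),
               "outside head")
})

test_that("slice extraction equals direct indexing and keeps coordinates", {
  set.seed(3)
  labels <- array(sample(1:5, 6 * 7 * 8, TRUE), c(6, 7, 8))
  ph <- voxel_phantom(labels, c(1, 2, 3))
  sl <- extract_slice(ph, "y", 4)
  expect_identical(sl$labels, labels[, 4, ])
  expect_identical(sl$spacing, c(1, 3))
  expect_identical(sl$axes, c("x", "z"))
  expect_equal(sl$fixed_coord, phantom_coords(ph)$y[4])
  expect_error(extract_slice(ph, "z", 9), "out of range")
  expect_error(extract_slice(ph, "w", 1))
})

test_that("an axial slice through the stroke centre shows the right disc", {
  ph <- generate_layered_head(spacing = 2)
  spec <- stroke_spec("haemorrhagic", centre = c(22, 0, 26.6), radius = 10)
  out <- insert_stroke(ph, spec)
  zi <- slice_index_at(out, "z", 26.6)
  sl <- extract_slice(out, "z", zi)
  co <- slice_coords(sl)
  hit <- which(sl$labels == 22L, arr.ind = TRUE)
  rmax <- max(sqrt((co$x[hit[, 1]] - 22)^2 + co$y[hit[, 2]]^2))
  dz <- sl$fixed_coord - 26.6
  expect_lt(abs(rmax - sqrt(100 - dz^2)), 2.1)  # within about one cell
})

test_that("slice embedding pads with air and preserves physical coordinates", {
  ph <- generate_layered_head(spacing = 4)
  sl <- extract_slice(ph, "z", slice_index_at(ph, "z", 0))
  big <- embed_slice(sl, c(160, 180))
  expect_gte(dim(big$labels)[1] * big$spacing[1] / 2, 160)
  co_old <- slice_coords(sl)
  co_new <- slice_coords(big)
  # the head's label pattern is unchanged on the shared coordinates
  ix <- match(round(co_old[[1]], 9), round(co_new[[1]], 9))
  iy <- match(round(co_old[[2]], 9), round(co_new[[2]], 9))
  expect_false(anyNA(c(ix, iy)))
  expect_identical(big$labels[ix, iy], sl$labels)
  pad <- big$labels
  pad[ix, iy] <- NA
  expect_true(all(pad[!is.na(pad)] == 1L))
})
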