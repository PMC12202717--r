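test_that("kernel size conventions give the documented footprints", {
  expect_equal(nrow(sg_offsets(sg_kernel("cuboid", 5))), 125L)
  expect_equal(nrow(sg_offsets(sg_kernel("cube", 10))), 11L^3)
  k <- sg_kernel("ellipsoid", 4)
  off <- sg_offsets(k)
  expect_true(all(rowSums((off / 4)^2) <= 1 + 1e-12))
  expect_true(max(off) == 4 && min(off) == -4)
  expect_error(sg_kernel("ellipsoid", 1), "cannot determine")
  expect_error(sg_kernel("cuboid", 5, degree = 1), "degree")
})

test_that("adaptation weights follow the Gaussian intensity rule", {
  k <- sg_kernel("cuboid", 5, weight = 0.05)
  n <- 125L
  # uniform reference: all weights 1 regardless of w
  w <- sg_fit_weights(k, ref_center = 3, ref_values = rep(3, n),
                      ref_range = 0)
  expect_true(all(w == 1))
  # huge w: weights approach 1 everywhere in-footprint
  khuge <- sg_kernel("cuboid", 5, weight = 1e6)
  w2 <- sg_fit_weights(khuge, 0, seq(0, 1, length.out = n), ref_range = 1)
  expect_true(all(w2 > 0.999999))
  # two-intensity step at w = 0.05: cross-boundary weights are negligible
  refs <- c(rep(0, 60), rep(1, 65))
  w3 <- sg_fit_weights(k, ref_center = 0, ref_values = refs, ref_range = 1)
  expect_equal(exp(-1 / (2 * 0.05^2)), max(w3[refs == 1]))
  expect_lt(max(w3[refs == 1]), 1e-3 * min(w3[refs == 0]))
  # background voxels weigh zero; all-zero weights are flagged
  w4 <- sg_fit_weights(k, foreground = c(TRUE, rep(FALSE, n - 1L)))
  expect_equal(w4[1], 1)
  expect_true(all(w4[-1] == 0))
  expect_error(sg_fit_weights(k, foreground = rep(FALSE, n)),
               "unreconstructable")
})

test_that("the Laplacian of a constant is zero and of a quadratic exact", {
  n <- 15L
  const <- volume_grid(array(5, c(n, n, n)), c(2, 2, 2.5), units = "rad")
  k <- sg_kernel("cuboid", 5)
  lap0 <- sg_laplacian(const, k)
  expect_true(all(abs(lap0$data) < 1e-7, na.rm = TRUE))
  # phi = 100 * |r|^2 has Laplacian 600 everywhere, clipping included
  ph <- quad_phase_volume(n, a = 100)
  lap <- sg_laplacian(ph, k)
  expect_true(all(abs(lap$data - 600) < 1e-6))
})

test_that("the Laplacian of a slow sinusoid matches -k^2 sin within 1%", {
  n <- 31L
  sp <- c(2, 2, 2)
  kx <- 0.1 / (2e-3)            # k*spacing = 0.1
  x <- ((seq_len(n) - 1) - (n - 1) / 2) * 2e-3
  ph <- volume_grid(array(rep(sin(kx * x), n * n), c(n, n, n)), sp,
                    units = "rad")
  lap <- sg_laplacian(ph, sg_kernel("cuboid", 5))
  i <- 10L
  expected <- -kx^2 * sin(kx * x[i])
  expect_equal(lap$data[i, 16, 16], expected, tolerance = 0.01)
})

test_that("sg_laplacian and sg_gradient equal a dense per-voxel WLS solve", {
  set.seed(42)
  n <- 9L
  sp <- c(2.3, 2.3, 2.5)
  vol <- array(rnorm(n^3), c(n, n, n))
  ref <- array(runif(n^3), c(n, n, n))
  fg <- array(TRUE, c(n, n, n))
  fg[1, 1, ] <- FALSE                      # ragged foreground
  v <- volume_grid(vol, sp, units = "rad")
  labs <- tissue_label_map(array(as.integer(fg), c(n, n, n)), sp)
  refv <- volume_grid(ref, sp)
  k <- sg_kernel("cuboid", 5, weight = 0.3)
  lap <- sg_laplacian(v, k, labels = labs, reference = refv)
  gr <- sg_gradient(v, k, labels = labs, reference = refv)
  attr(vol, "spacing_mm") <- sp
  rng <- diff(range(ref[fg]))
  for (pt in list(c(3, 3, 3), c(5, 5, 5), c(2, 8, 4), c(9, 9, 9))) {
    o_lap <- wls_oracle_voxel(vol, pt[1], pt[2], pt[3], 2, w = 0.3,
                              ref = ref, ref_range = rng, fg = fg,
                              what = "laplacian")
    o_gr <- wls_oracle_voxel(vol, pt[1], pt[2], pt[3], 2, w = 0.3,
                             ref = ref, ref_range = rng, fg = fg,
                             what = "gradient")
    expect_equal(lap$data[pt[1], pt[2], pt[3]], o_lap, tolerance = 1e-10)
    expect_equal(c(gr$ddx$data[pt[1], pt[2], pt[3]],
                   gr$ddy$data[pt[1], pt[2], pt[3]],
                   gr$ddz$data[pt[1], pt[2], pt[3]]),
                 o_gr, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # background voxels are NA
  expect_true(all(is.na(lap$data[1, 1, ])))
})

test_that("gradients reproduce linear and quadratic fields exactly", {
  n <- 11L
  sp <- c(2, 3, 4)
  x_m <- (seq_len(n) - 1) * sp[1] * 1e-3
  lin <- volume_grid(array(rep(7 * x_m, n * n), c(n, n, n)), sp)
  k <- sg_kernel("ellipsoid", 4)
  gr <- sg_gradient(lin, k)
  expect_true(all(abs(gr$ddx$data - 7) < 1e-9))
  expect_true(all(abs(gr$ddy$data) < 1e-9))
  expect_true(all(abs(gr$ddz$data) < 1e-9))
  # quadratic in z: d/dz = 2*a*z exact at all voxels
  z_m <- (seq_len(n) - 1) * sp[3] * 1e-3
  quad <- volume_grid(array(rep(50 * z_m^2, each = n * n), c(n, n, n)), sp)
  gq <- sg_gradient(quad, k)
  expected <- array(rep(100 * z_m, each = n * n), c(n, n, n))
  expect_equal(gq$ddz$data, expected, tolerance = 1e-8, ignore_attr = TRUE)
  # constant field: zero gradient
  gc <- sg_gradient(volume_grid(array(2, c(n, n, n)), sp), k)
  expect_true(all(abs(gc$ddx$data) < 1e-10))
})

test_that("complex fields share fit weights between parts", {
  set.seed(5)
  n <- 9L
  re <- array(rnorm(n^3), c(n, n, n))
  im <- array(rnorm(n^3), c(n, n, n))
  sp <- c(2, 2, 2)
  vc <- volume_grid(array(complex(real = re, imaginary = im), c(n, n, n)), sp)
  k <- sg_kernel("cuboid", 5)
  gc <- sg_gradient(vc, k)
  gre <- sg_gradient(volume_grid(re, sp), k)
  gim <- sg_gradient(volume_grid(im, sp), k)
  expect_equal(Re(gc$ddx$data), gre$ddx$data, tolerance = 1e-12)
  expect_equal(Im(gc$ddx$data), gim$ddx$data, tolerance = 1e-12)
})
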