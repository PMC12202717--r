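test_that("volume_grid enforces its geometric invariants", {
  expect_error(volume_grid(matrix(1, 4, 4), c(1, 1, 1)), "3D")
  expect_error(volume_grid(array(1, c(4, 4, 4)), c(1, -1, 1)), "positive")
  expect_error(volume_grid(array(1i, c(2, 2, 2)), c(1, 1, 1), units = "S/m"),
               "complex")
  v <- volume_grid(array(1, c(4, 4, 4)), c(2.3, 2.3, 2.5), units = "rad")
  expect_identical(dim(v), c(4L, 4L, 4L))
})

test_that("voxel/world coordinate round trip is the identity in bounds", {
  v <- volume_grid(array(0, c(12, 10, 8)), c(2.3, 2.3, 2.5),
                   origin = c(-10, 5, 2))
  idx <- as.matrix(expand.grid(c(1, 5, 12), c(1, 10), c(3, 8)))
  back <- world_to_voxel(v, voxel_to_world(v, idx))
  expect_equal(back, unname(idx), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NIfTI write/read round-trips values, spacing and origin", {
  set.seed(7)
  v <- volume_grid(array(rnorm(30 * 25 * 10), c(30, 25, 10)),
                   c(2.3, 2.3, 2.5), origin = c(4, -8, 12), units = "rad")
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  r <- read_volume(f, "rad")
  expect_equal(r$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-5)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
  expect_identical(r$units, "rad")
})

test_that("complex volumes round-trip through the magnitude/phase pair", {
  set.seed(8)
  z <- array(complex(real = rnorm(1000), imaginary = rnorm(1000)),
             c(10, 10, 10))
  v <- volume_grid(z, c(2, 2, 2), units = "a.u.")
  f <- file.path(tempdir(), "cplx.nii")
  paths <- write_volume(v, f)
  expect_length(paths, 3L)
  r <- read_volume(f, "a.u.")
  expect_equal(r$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("read_volume rejects missing files, 2D payloads, bad spacing", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 6, 6)), f)
  expect_error(read_volume(f), "3D")
  expect_error(write_volume(volume_grid(array(1, c(2, 2, 2)), c(1, 1, 1)),
                            "/nonexistent-dir/x.nii"), "write")
})

test_that("resampling is the identity on the reference grid and idempotent", {
  set.seed(9)
  v <- volume_grid(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(2, 2, 2))
  r <- resample_to_reference(v, v, "linear")
  expect_identical(r$data, v$data)
  coarse <- volume_grid(array(rnorm(5 * 5 * 5), c(5, 5, 5)), c(4, 4, 4))
  once <- resample_to_reference(coarse, v, "linear")
  twice <- resample_to_reference(once, v, "linear")
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("constant volumes are fixed points of linear resampling", {
  mov <- volume_grid(array(3.7, c(10, 10, 10)), c(4, 4, 5))
  ref <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  out <- resample_to_reference(mov, ref, "linear")
  inside <- out$data != 0
  expect_true(any(inside))
  expect_true(all(abs(out$data[inside] - 3.7) < 1e-12))
})

test_that("trilinear resampling matches a direct evaluation at a point", {
  set.seed(10)
  mov <- volume_grid(array(rnorm(64 * 64 * 30), c(64, 64, 30)), c(4, 4, 5))
  ref <- volume_grid(array(0, c(128, 128, 35)), c(2.3, 2.3, 2.5))
  out <- resample_to_reference(mov, ref, "linear")
  # hand evaluation at the reference centre voxel
  ctr <- c(64L, 64L, 18L)
  wc <- voxel_to_world(ref, matrix(ctr, 1))
  ci <- as.numeric(world_to_voxel(mov, wc))
  f <- floor(ci); t <- ci - f
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    acc <- acc + prod(ifelse(c(dx, dy, dz) == 1, t, 1 - t)) *
      mov$data[f[1] + dx, f[2] + dy, f[3] + dz]
  expect_equal(out$data[ctr[1], ctr[2], ctr[3]], acc, tolerance = 1e-12)
})

test_that("nearest-mode label resampling emits only input codes", {
  set.seed(11)
  lab <- tissue_label_map(array(sample(0:3, 6 * 6 * 6, TRUE), c(6, 6, 6)),
                          c(4, 4, 5))
  ref <- volume_grid(array(0, c(13, 13, 13)), c(2, 2, 2))
  out <- resample_to_reference(lab, ref, "nearest")
  expect_s3_class(out, "tissue_label_map")
  expect_true(all(out$data %in% 0:3))
  expect_error(resample_to_reference(lab, ref, "linear"), "nearest")
})

test_that("disjoint physical extents raise an empty-overlap error", {
  mov <- volume_grid(array(1, c(4, 4, 4)), c(1, 1, 1), origin = c(0, 0, 0))
  ref <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1),
                     origin = c(100, 100, 100))
  expect_error(resample_to_reference(mov, ref), "overlap")
})

test_that("region interior masks erode by the requested radius", {
  lab <- array(0L, c(20, 20, 9))
  lab[5:16, 5:16, ] <- 1L
  tl <- tissue_label_map(lab, c(2, 2, 2))
  int <- region_interior_mask(tl, 3)
  expect_true(all(lab[int] == 1L))
  # voxels within 3 of the label boundary are excluded...
  expect_false(int[5, 10, 5])
  expect_false(int[8, 5, 5])
  # ...but the volume edge (region continues past it) does not disqualify
  expect_true(int[10, 10, 1])
  expect_true(int[8, 8, 5])
})
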