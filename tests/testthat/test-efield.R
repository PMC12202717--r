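make_uniform_setup <- function(n = 13L, sp = c(2, 2, 2), sigma = 1,
                               eps_r = 1) {
  list(labels = all_fg_labels(n, sp),
       sigma = volume_grid(array(sigma, c(n, n, n)), sp, units = "S/m"),
       eps = electrical_properties_table(tissue = "t", code = 1L,
                                         sigma = sigma, eps_r = eps_r),
       n = n, sp = sp)
}

test_that("B1+ assembly implements magnitude * exp(i phase/2)", {
  sp <- c(2, 2, 2)
  m <- volume_grid(array(2, c(4, 4, 4)), sp, units = "a.u.")
  p0 <- volume_grid(array(0, c(4, 4, 4)), sp, units = "rad")
  ppi <- volume_grid(array(pi, c(4, 4, 4)), sp, units = "rad")
  expect_equal(assemble_b1plus(m, p0)$data[1], 2 + 0i)
  expect_equal(assemble_b1plus(m, ppi)$data[1], 2i)
  set.seed(3)
  mr <- volume_grid(array(runif(64), c(4, 4, 4)), sp)
  pr <- volume_grid(array(rnorm(64), c(4, 4, 4)), sp, units = "rad")
  b1 <- assemble_b1plus(mr, pr)
  expect_equal(Mod(b1$data), mr$data, tolerance = 1e-12)
  expect_equal(Arg(b1$data), pr$data / 2, tolerance = 1e-12)
  mneg <- volume_grid(array(-1, c(4, 4, 4)), sp)
  expect_error(assemble_b1plus(mneg, p0), "non-negative")
})

test_that("a spatially constant B1+ induces no E-field", {
  s <- make_uniform_setup()
  b1 <- assemble_b1plus(volume_grid(array(1, c(s$n, s$n, s$n)), s$sp),
                        volume_grid(array(0, c(s$n, s$n, s$n)), s$sp))
  E <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels)
  expect_true(all(Mod(E$Ex$data) < 1e-5))
  expect_true(all(Mod(E$Ey$data) < 1e-5))
  expect_true(all(Mod(E$Ez$data) < 1e-5))
})

test_that("a linear-in-z B1+ matches the Ampere closed form", {
  cfg <- physics_config()
  s <- make_uniform_setup()
  z <- (seq_len(s$n) - 1) * s$sp[3] * 1e-3
  b1m <- volume_grid(array(rep(z, each = s$n^2), c(s$n, s$n, s$n)), s$sp)
  b1 <- assemble_b1plus(b1m, volume_grid(array(0, c(s$n, s$n, s$n)), s$sp))
  E <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels, cfg)
  y <- 1 + 1i * cfg$omega * cfg$eps0 * 1      # admittance, sigma 1, eps_r 1
  i <- 7L
  expect_equal(E$Ex$data[i, i, i], 1i / (cfg$mu0 * y), tolerance = 1e-8)
  expect_equal(E$Ey$data[i, i, i], 1 / (cfg$mu0 * y), tolerance = 1e-8)
  expect_lt(Mod(E$Ez$data[i, i, i]), 1e-6 * Mod(E$Ex$data[i, i, i]))
  # |Ex| = |Ey| = 1/(mu0 |y|), the textbook value
  expect_equal(Mod(E$Ex$data[i, i, i]), 1 / (cfg$mu0 * Mod(y)),
               tolerance = 1e-8)
})

test_that("E scales linearly with B1+ and inversely with the admittance", {
  cfg <- physics_config()
  s <- make_uniform_setup()
  set.seed(12)
  co <- (seq_len(s$n) - 1) * 2e-3
  smooth <- outer(outer(co, co^2 / 0.01, "+"), co, "*") / 10
  b1m <- volume_grid(smooth + 1, s$sp)
  ph <- volume_grid(array(0.3, c(s$n, s$n, s$n)), s$sp, units = "rad")
  b1 <- assemble_b1plus(b1m, ph)
  E1 <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels, cfg)
  b1_scaled <- assemble_b1plus(volume_grid(3 * b1m$data, s$sp), ph)
  E3 <- efield_from_b1plus(b1_scaled, s$sigma, s$eps, s$labels, cfg)
  expect_equal(E3$Ex$data, 3 * E1$Ex$data, tolerance = 1e-9)
  expect_equal(E3$Ez$data, 3 * E1$Ez$data, tolerance = 1e-9)
  # doubling sigma (with negligible omega*eps) halves |E|
  s2 <- make_uniform_setup(sigma = 2)
  E2 <- efield_from_b1plus(b1, s2$sigma, s2$eps, s2$labels, cfg)
  i <- 7L
  expect_equal(Mod(E2$Ex$data[i, i, i]) * 2, Mod(E1$Ex$data[i, i, i]),
               tolerance = 1e-3)
})

test_that("the time convention conjugates E but leaves |E| and SAR fixed", {
  s <- make_uniform_setup(eps_r = 60)
  co <- (seq_len(s$n) - 1) * 2e-3
  b1m <- volume_grid(array(1 + 5 * outer(outer(co, co, "+"), co, "+"),
                           c(s$n, s$n, s$n)), s$sp)
  ph <- volume_grid(array(rep(co, each = s$n^2), c(s$n, s$n, s$n)) * 20,
                    s$sp, units = "rad")
  b1 <- assemble_b1plus(b1m, ph)
  Ep <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels,
                           physics_config(time_convention = "+iwt"))
  Em <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels,
                           physics_config(time_convention = "-iwt"))
  expect_equal(Mod(Ep$Ex$data), Mod(Em$Ex$data), tolerance = 1e-12)
  expect_equal(Mod(Ep$Ez$data), Mod(Em$Ez$data), tolerance = 1e-12)
  sar_p <- pointwise_sar(Ep, s$sigma)
  sar_m <- pointwise_sar(Em, s$sigma)
  expect_equal(sar_p$data, sar_m$data, tolerance = 1e-12)
})

test_that("components match a finite-difference curl oracle", {
  cfg <- physics_config()
  s <- make_uniform_setup(n = 11L, sigma = 0.6, eps_r = 50)
  n <- s$n
  co <- (seq_len(n) - 1) * 2e-3
  # complex quadratic B1+: SG gradients and central differences both exact
  re <- outer(outer(3 * co^2, 2 * co, "+"), co, "+")
  im <- outer(outer(co, co^2 * 5, "+"), 2 * co, "+")
  b1dat <- array(complex(real = re, imaginary = im), c(n, n, n))
  b1 <- structure(list(data = b1dat, spacing = s$sp, origin = c(0, 0, 0),
                       units = "a.u."),
                  class = c("complex_b1_map", "volume_grid"))
  E <- efield_from_b1plus(b1, s$sigma, s$eps, s$labels, cfg)
  y <- 0.6 + 1i * cfg$omega * cfg$eps0 * 50
  for (pt in list(c(6, 6, 6), c(3, 8, 5))) {
    i <- pt[1]; j <- pt[2]; k <- pt[3]
    # curl of (Bx, By, 0) with Bx = B1+, By = -i B1+
    dBy <- fd_gradient_voxel(-1i * b1dat, i, j, k, s$sp)
    dBx <- fd_gradient_voxel(b1dat, i, j, k, s$sp)
    curl <- c(-dBy[3], dBx[3], dBy[1] - dBx[2])
    expected <- curl / (cfg$mu0 * y)
    expect_equal(E$Ex$data[i, j, k], expected[1], tolerance = 1e-6)
    expect_equal(E$Ey$data[i, j, k], expected[2], tolerance = 1e-6)
    expect_equal(E$Ez$data[i, j, k], expected[3], tolerance = 1e-6)
  }
})
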