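# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately written without reusing the package's
# internal code paths: dense per-voxel least squares via lm.wfit, central
# finite differences, and brute-force recounts.

# dense weighted least-squares fit of a degree-2 polynomial at one voxel;
# returns the named quantity ("laplacian", "gradient", "smooth") or NA when
# underdetermined. spacing in mm; fit coordinates in metres.
wls_oracle_voxel <- function(vol, i, j, k, half_width, shape = "cuboid",
                             w = NULL, ref = NULL, ref_range = NULL,
                             fg = NULL, what = "laplacian") {
  d <- dim(vol)
  if (is.null(fg)) fg <- array(TRUE, dim = d)
  rows <- list()
  vals <- c()
  wts <- c()
  r0 <- if (!is.null(ref)) ref[i, j, k] else 0
  for (dz in -half_width:half_width)
    for (dy in -half_width:half_width)
      for (dx in -half_width:half_width) {
        if (shape == "ellipsoid" &&
            (dx^2 + dy^2 + dz^2) / half_width^2 > 1 + 1e-12) next
        ii <- i + dx; jj <- j + dy; kk <- k + dz
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        if (!fg[ii, jj, kk] || is.na(vol[ii, jj, kk])) next
        wt <- 1
        if (!is.null(w) && !is.null(ref)) {
          s <- w * ref_range
          wt <- exp(-(ref[ii, jj, kk] - r0)^2 / (2 * s^2))
        }
        x <- dx * attr(vol, "spacing_mm")[1] * 1e-3
        y <- dy * attr(vol, "spacing_mm")[2] * 1e-3
        z <- dz * attr(vol, "spacing_mm")[3] * 1e-3
        rows[[length(rows) + 1L]] <-
          c(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
        vals <- c(vals, vol[ii, jj, kk])
        wts <- c(wts, wt)
      }
  X <- do.call(rbind, rows)
  if (is.null(X) || nrow(X) < 10L) return(NA_real_)
  fit <- stats::lm.wfit(X, vals, wts)
  cf <- unname(fit$coefficients)
  if (any(is.na(cf))) return(NA_real_)
  switch(what,
         laplacian = 2 * (cf[5] + cf[6] + cf[7]),
         gradient = cf[2:4],
         smooth = cf[1])
}

# central-difference Laplacian at one interior voxel, spacing in mm
fd_laplacian_voxel <- function(a, i, j, k, spacing_mm) {
  s <- spacing_mm * 1e-3
  (a[i + 1, j, k] - 2 * a[i, j, k] + a[i - 1, j, k]) / s[1]^2 +
    (a[i, j + 1, k] - 2 * a[i, j, k] + a[i, j - 1, k]) / s[2]^2 +
    (a[i, j, k + 1] - 2 * a[i, j, k] + a[i, j, k - 1]) / s[3]^2
}

# central-difference first derivative along one axis (1/m)
fd_gradient_voxel <- function(a, i, j, k, spacing_mm) {
  s <- spacing_mm * 1e-3
  c((a[i + 1, j, k] - a[i - 1, j, k]) / (2 * s[1]),
    (a[i, j + 1, k] - a[i, j - 1, k]) / (2 * s[2]),
    (a[i, j, k + 1] - a[i, j, k - 1]) / (2 * s[3]))
}

# brute-force 10-g cube average at every tissue voxel (counts tissue mass,
# averages defined SAR), returned as list(value, mass, h)
brute_10g <- function(sar, tissue, spacing_mm, density, target_g, hmax) {
  d <- dim(sar)
  vm <- density * prod(spacing_mm) * 1e-6
  out <- array(NA_real_, d); mass <- array(NA_real_, d)
  hh <- array(NA_integer_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!tissue[i, j, k]) next
    for (h in 0:hmax) {
      xs <- max(1, i - h):min(d[1], i + h)
      ys <- max(1, j - h):min(d[2], j + h)
      zs <- max(1, k - h):min(d[3], k + h)
      tt <- tissue[xs, ys, zs]
      m <- sum(tt) * vm
      if (m >= target_g) {
        sv <- sar[xs, ys, zs]
        ok <- tt & !is.na(sv)
        out[i, j, k] <- sum(sv[ok]) / sum(ok)
        mass[i, j, k] <- m
        hh[i, j, k] <- h
        break
      }
    }
  }
  list(value = out, mass = mass, h = hh)
}

# uniform-conductivity cube phantom with a quadratic forward phase, no noise
quad_phase_volume <- function(n = 15L, spacing = c(2, 2, 2.5), a = 100) {
  co <- lapply(1:3, function(ax) ((seq_len(n) - 1) - (n - 1) / 2) *
                 spacing[ax] * 1e-3)
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  volume_grid(a * r2, spacing, units = "rad")
}

all_fg_labels <- function(n, spacing = c(2, 2, 2.5)) {
  tissue_label_map(array(1L, dim = c(n, n, n)), spacing)
}
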