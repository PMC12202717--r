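#' Pointwise specific absorption rate
#'
#' `SAR = sigma * (|Ex|^2 + |Ey|^2 + |Ez|^2) / (2 * rho)`, treating the
#' stored complex amplitudes as peak values of the time-harmonic field (the
#' factor 2 converts to the time average).
#'
#' @param E an `efield_map` from [efield_from_b1plus()].
#' @param sigma conductivity `volume_grid` (S/m).
#' @param cfg a [physics_config()] supplying the mass density.
#' @return SAR `volume_grid` in W/kg.
#' @export
pointwise_sar <- function(E, sigma, cfg = physics_config()) {
  e2 <- efield_magnitude2(E)
  stop_if_geometry_differs(e2, sigma)
  with_data(sigma, sigma$data * e2$data / (2 * cfg$rho), units = "W/kg")
}

#' Mask-renormalised Gaussian smoothing
#'
#' Separable Gaussian convolution restricted to the foreground: the volume
#' and the mask are convolved with the same kernel and the ratio is taken,
#' so background (and undefined) voxels never leak into the foreground.
#' `sigma_g = 0` is the identity. The kernel is evaluated on the voxel
#' lattice out to `max(1, ceiling(4*sigma_g))` voxels and normalised.
#'
#' @param sar `volume_grid` to smooth.
#' @param sigma_g Gaussian SD in voxel units (default 0.4).
#' @param labels optional `tissue_label_map`; nonzero codes are foreground.
#' @return smoothed `volume_grid`; background and `NA` voxels unchanged.
#' @export
gaussian_smooth <- function(sar, sigma_g = 0.4, labels = NULL) {
  if (sigma_g < 0) stop("sigma_g must be >= 0")
  if (sigma_g == 0) return(sar)
  fg <- if (is.null(labels)) array(TRUE, dim = dim(sar$data)) else
    foreground_mask(labels)
  def <- fg & !is.na(sar$data)
  r <- max(1L, ceiling(4 * sigma_g))
  kern <- stats::dnorm(-r:r, sd = sigma_g)
  kern <- kern / sum(kern)
  num <- sar$data
  num[!def] <- 0
  den <- array(as.numeric(def), dim = dim(sar$data))
  for (axis in 1:3) {
    num <- convolve_axis(num, kern, axis)
    den <- convolve_axis(den, kern, axis)
  }
  out <- sar$data
  out[def] <- num[def] / den[def]
  with_data(sar, out)
}

# 1D convolution of a 3D array along one axis, zero padding
convolve_axis <- function(a, kern, axis) {
  r <- (length(kern) - 1L) / 2L
  d <- dim(a)
  out <- array(0, dim = d)
  for (s in -r:r) {
    w <- kern[s + r + 1L]
    n <- d[axis]
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    idx_to <- which(ok)
    idx_from <- src[ok]
    if (axis == 1) out[idx_to, , ] <- out[idx_to, , ] + w * a[idx_from, , ]
    else if (axis == 2) out[, idx_to, ] <- out[, idx_to, ] + w * a[, idx_from, ]
    else out[, , idx_to] <- out[, , idx_to] + w * a[, , idx_from]
  }
  out
}

#' Remove high outliers above mean + k standard deviations
#'
#' The mean and SD are computed once over defined foreground voxels (no
#' iteration); voxels strictly above `mean + k*SD` become undefined (`NA`)
#' and are excluded from all downstream statistics and maps. With the
#' default `k = 9` only extreme reconstruction artefacts are removed while
#' legitimate hotspots survive.
#'
#' @param v `volume_grid`.
#' @param k threshold multiplier, > 0.
#' @param labels optional `tissue_label_map` foreground.
#' @return list with `volume` (outliers set `NA`), `count_removed`, and
#'   `threshold`.
#' @export
remove_outliers <- function(v, k = 9, labels = NULL) {
  if (k <= 0) stop("k must be > 0")
  fg <- if (is.null(labels)) array(TRUE, dim = dim(v$data)) else
    foreground_mask(labels)
  def <- fg & !is.na(v$data)
  vals <- v$data[def]
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (is.na(sdv)) sdv <- 0          # single defined voxel
  thr <- mu + k * sdv
  drop <- def & v$data > thr
  out <- v$data
  out[drop] <- NA_real_
  list(volume = with_data(v, out), count_removed = sum(drop),
       threshold = thr)
}

#' Apply tissue-specific SAR correction factors
#'
#' Voxelwise multiplication by the factor of the voxel's tissue;
#' background voxels are untouched. The correction repairs the systematic
#' underestimation of B1+-only SAR.
#'
#' @param sar SAR `volume_grid` (W/kg).
#' @param labels a `tissue_label_map` on the same grid.
#' @param table a [correction_factor_table()].
#' @param which `"sar"` (pointwise factors) or `"sar10g"`.
#' @return corrected `volume_grid`.
#' @export
apply_correction <- function(sar, labels, table = correction_factor_table(),
                             which = c("sar", "sar10g")) {
  which <- match.arg(which)
  stop_if_geometry_differs(sar, labels)
  col <- if (which == "sar") "sar_factor" else "sar10g_factor"
  present <- setdiff(unique(as.vector(labels$data)), 0L)
  missing <- setdiff(present, table$code)
  if (length(missing)) {
    nm <- names(labels$code_table)[match(missing, labels$code_table)]
    stop("no ", which, " correction factor for tissue(s): ",
         paste(ifelse(is.na(nm), missing, nm), collapse = ", "))
  }
  out <- sar$data
  for (i in seq_len(nrow(table))) {
    m <- labels$data == table$code[i]
    out[m] <- sar$data[m] * table[[col]][i]
  }
  with_data(sar, out)
}

#' Normalise a map to its post-outlier maximum
#'
#' Applies [remove_outliers()] with `k = 9` and divides by the surviving
#' maximum, mapping the map into `[0, 1]` for shape comparison between
#' differently scaled SAR maps.
#'
#' @param v `volume_grid` with at least one defined voxel.
#' @param labels optional `tissue_label_map` foreground.
#' @return normalised `volume_grid` (outliers `NA`).
#' @export
normalize_for_comparison <- function(v, labels = NULL) {
  ro <- remove_outliers(v, k = 9, labels = labels)
  fg <- if (is.null(labels)) array(TRUE, dim = dim(v$data)) else
    foreground_mask(labels)
  def <- fg & !is.na(ro$volume$data)
  if (!any(def)) stop("no defined voxels to normalise")
  mx <- max(ro$volume$data[def])
  with_data(v, ro$volume$data / mx, units = "")
}
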