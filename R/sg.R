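#' 3D Savitzky-Golay kernel specification
#'
#' Describes the neighbourhood and local polynomial used to evaluate smoothed
#' values, gradients and Laplacians on noisy volumes. The `size` argument
#' follows the conventions of the standard workflow: for `"cuboid"` and
#' `"cube"` shapes it is the full footprint extent in voxels, realised as the
#' symmetric footprint of half-extent `floor(size/2)` per axis (size 5 gives
#' a 5x5x5 box, size 10 an 11x11x11 box); for `"ellipsoid"` it is the
#' semi-axis in voxels (size 4 gives a 9-voxel full width masked to the
#' ellipsoid).
#'
#' @param shape `"cuboid"`, `"cube"` or `"ellipsoid"`.
#' @param size footprint size parameter (see above).
#' @param degree polynomial degree of the local fit; must be 2 for any kernel
#'   used to evaluate a Laplacian or gradient, 0 for a plain weighted mean.
#' @param weight anatomical adaptation weight `w` (dimensionless), or `NULL`
#'   for no adaptation. Footprint voxel `j` is weighted
#'   `exp(-(R_j - R_0)^2 / (2 (w * dR)^2))` where `R` is a reference image,
#'   `R_0` its value at the centre voxel and `dR` its range over the
#'   foreground.
#' @return object of class `sg_kernel`.
#' @export
sg_kernel <- function(shape = c("cuboid", "cube", "ellipsoid"), size = 5L,
                      degree = 2L, weight = NULL) {
  shape <- match.arg(shape)
  if (!degree %in% c(0L, 2L)) stop("degree must be 0 or 2")
  hw <- if (shape == "ellipsoid") as.integer(size) else as.integer(floor(size / 2))
  if (hw < 1L) stop("kernel size too small")
  k <- structure(list(shape = shape, size = as.integer(size), degree = degree,
                      half_width = hw, weight = weight), class = "sg_kernel")
  noff <- nrow(sg_offsets(k))
  if (noff <= n_monomials(degree))
    stop("kernel footprint (", noff, " voxels) cannot determine a degree-",
         degree, " fit")
  k
}

n_monomials <- function(degree) if (degree == 0L) 1L else 10L

#' Integer voxel offsets of a kernel footprint
#'
#' @param kernel an [sg_kernel()].
#' @return n x 3 integer matrix of offsets about the centre voxel.
#' @export
sg_offsets <- function(kernel) {
  hw <- kernel$half_width
  g <- as.matrix(expand.grid(x = -hw:hw, y = -hw:hw, z = -hw:hw))
  if (kernel$shape == "ellipsoid")
    g <- g[rowSums((g / hw)^2) <= 1 + 1e-12, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# monomial design matrix at the footprint offsets. The fit runs in
# coordinates normalised by the footprint extent (order-1 numbers keep the
# normal equations well conditioned); callers divide the returned
# coefficients by the scale (mm) once per derivative order and convert to
# SI. The scale is returned as an attribute.
sg_design <- function(offsets, spacing_mm, degree) {
  scale_mm <- max(apply(abs(offsets), 2L, max) * spacing_mm)
  xyz <- sweep(offsets, 2L, spacing_mm / scale_mm, "*")
  X <- if (degree == 0L) matrix(1, nrow(offsets), 1L) else
    cbind(1, xyz[, 1], xyz[, 2], xyz[, 3],
          xyz[, 1]^2, xyz[, 2]^2, xyz[, 3]^2,
          xyz[, 1] * xyz[, 2], xyz[, 1] * xyz[, 3], xyz[, 2] * xyz[, 3])
  attr(X, "scale_mm") <- scale_mm
  X
}

#' Anatomically adapted per-voxel fit weights
#'
#' The concrete weighting rule used by every Savitzky-Golay operation:
#' background voxels weigh 0; without adaptation every in-footprint
#' foreground voxel weighs 1; with adaptation, voxel `j` weighs
#' `exp(-(R_j - R_0)^2 / (2 (w * dR)^2))` with `R_0` the reference value at
#' the centre voxel and `dR` the reference range over the foreground. A
#' footprint with all-zero weights (isolated voxel) is flagged
#' unreconstructable.
#'
#' @param kernel an [sg_kernel()].
#' @param ref_center reference-image value at the centre voxel.
#' @param ref_values reference-image values over the footprint.
#' @param foreground logical vector over the footprint (default all `TRUE`).
#' @param ref_range reference range `dR` over the volume foreground.
#' @return numeric weights in `[0, 1]`, one per footprint voxel.
#' @export
sg_fit_weights <- function(kernel, ref_center = NULL, ref_values = NULL,
                           foreground = NULL, ref_range = NULL) {
  n <- if (!is.null(ref_values)) length(ref_values)
  else if (!is.null(foreground)) length(foreground)
  else nrow(sg_offsets(kernel))
  if (is.null(foreground)) foreground <- rep(TRUE, n)
  w <- as.numeric(foreground)
  if (!is.null(kernel$weight) && !is.null(ref_values)) {
    s <- kernel$weight * (ref_range %||% diff(range(ref_values)))
    if (is.finite(s) && s > 0)
      w <- w * exp(-(ref_values - ref_center)^2 / (2 * s^2))
  }
  if (all(w == 0))
    stop("all-zero weights: voxel is unreconstructable")
  w
}

# shared driver for the compiled weighted-fit kernel
sg_apply <- function(vol, kernel, labels = NULL, reference = NULL, want) {
  d <- dim(vol$data)
  fg <- if (is.null(labels)) array(TRUE, dim = d) else foreground_mask(labels)
  if (!is.null(labels)) stop_if_geometry_differs(vol, labels)
  refv <- numeric(0)
  sscale <- -1
  if (!is.null(reference) && !is.null(kernel$weight)) {
    stop_if_geometry_differs(vol, reference)
    rng <- diff(range(reference$data[fg]))
    if (rng > 0) {
      refv <- as.numeric(reference$data)
      sscale <- kernel$weight * rng
    }
  }
  off <- sg_offsets(kernel)
  X <- sg_design(off, vol$spacing, kernel$degree)
  cplx <- is.complex(vol$data)
  re <- if (cplx) as.numeric(Re(vol$data)) else as.numeric(vol$data)
  im <- if (cplx) as.numeric(Im(vol$data)) else numeric(0)
  res <- sg_fit_cpp(re, im, as.integer(d), as.logical(fg), refv, sscale,
                    off, X, as.integer(want))
  res$scale_mm <- attr(X, "scale_mm")
  res
}

#' Savitzky-Golay Laplacian of a phase volume
#'
#' At each foreground voxel a weighted least-squares degree-2 polynomial is
#' fitted over the kernel footprint in physical (metre) coordinates; the
#' output is `2 * (a_xx + a_yy + a_zz)` from the fitted quadratic
#' coefficients. Voxels with underdetermined or singular fits are returned
#' as `NA` (unreconstructable), as are background voxels.
#'
#' @param phase `volume_grid` in rad.
#' @param kernel degree-2 [sg_kernel()].
#' @param labels optional `tissue_label_map`; nonzero codes are foreground.
#'   Without it the whole volume is treated as foreground.
#' @param reference optional `volume_grid` for anatomical adaptation (used
#'   only when the kernel carries a `weight`).
#' @return `volume_grid` in rad/m^2.
#' @export
sg_laplacian <- function(phase, kernel, labels = NULL, reference = NULL) {
  if (kernel$degree < 2L) stop("a Laplacian needs a degree-2 kernel")
  res <- sg_apply(phase, kernel, labels, reference, want = 2L)
  # fit runs in footprint-normalised coordinates: rescale to 1/m^2
  f <- 1e6 / res$scale_mm^2
  with_data(phase, array(res$val_re * f, dim = dim(phase$data)),
            units = "rad/m^2")
}

#' Savitzky-Golay first derivatives of a (complex) volume
#'
#' The three first-order coefficients of the local degree-2 weighted fit, in
#' 1/m per unit of the input. For complex input the real and imaginary parts
#' share the fit weights and normal matrix.
#'
#' @inheritParams sg_laplacian
#' @param field real or complex `volume_grid`.
#' @return list with `volume_grid`s `ddx`, `ddy`, `ddz`.
#' @export
sg_gradient <- function(field, kernel, labels = NULL, reference = NULL) {
  if (kernel$degree < 2L) stop("gradients need a degree-2 kernel")
  res <- sg_apply(field, kernel, labels, reference, want = 1L)
  d <- dim(field$data)
  f <- 1e3 / res$scale_mm    # normalised fit coordinates -> 1/m
  mk <- function(rep, imp) {
    dat <- if (is.complex(field$data))
      array(complex(real = rep, imaginary = imp) * f, dim = d)
    else array(rep * f, dim = d)
    with_data(field, dat, units = paste0(field$units, "/m"))
  }
  if (is.complex(field$data))
    list(ddx = mk(res$gx_re, res$gx_im), ddy = mk(res$gy_re, res$gy_im),
         ddz = mk(res$gz_re, res$gz_im))
  else
    list(ddx = mk(res$gx_re), ddy = mk(res$gy_re), ddz = mk(res$gz_re))
}

# degree-0 weighted local mean with the same weighting rules
sg_weighted_mean <- function(vol, kernel, labels = NULL, reference = NULL) {
  k0 <- kernel
  k0$degree <- 0L
  res <- sg_apply(vol, k0, labels, reference, want = 0L)
  with_data(vol, array(res$val_re, dim = dim(vol$data)))
}
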