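#' Volumetric scalar or complex field on a regular grid
#'
#' `volume_grid` is the carrier for every map in the pipeline: B1+ magnitude,
#' transceive phase, conductivity, SAR. The data array is indexed `[x, y, z]`;
#' `spacing` and `origin` are in millimetres, so that the physical (world)
#' coordinate of voxel `(i, j, k)` (1-based) is `origin + (c(i,j,k) - 1) *
#' spacing`. Differential operators convert spacing to metres internally.
#'
#' @param data numeric or complex 3D array.
#' @param spacing length-3 positive numeric, voxel size in mm.
#' @param origin length-3 numeric, world coordinate of voxel (1,1,1) in mm.
#' @param units free-text unit tag ("rad", "S/m", "W/kg", "a.u.", ...).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0), units = "") {
  if (is.vector(data)) data <- array(data, dim = c(length(data), 1L, 1L))
  v <- structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = as.character(units)[1L]),
    class = "volume_grid")
  validate_volume_grid(v)
  v
}

#' @rdname volume_grid
#' @param v a `volume_grid`.
#' @export
validate_volume_grid <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  d <- dim(v$data)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("volume_grid data must be a 3D array with each axis >= 1")
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("spacing must be strictly positive on all three axes")
  if (length(v$origin) != 3L || any(!is.finite(v$origin)))
    stop("origin must be a finite length-3 vector")
  if (is.complex(v$data) && v$units %in% c("S/m", "W/kg"))
    stop("complex-valued volumes cannot carry units ", v$units)
  invisible(v)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %dx%dx%d voxels, spacing (%g, %g, %g) mm%s%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (nzchar(x$units)) paste0(", units: ", x$units) else "",
              if (is.complex(x$data)) ", complex" else ""))
  invisible(x)
}

# clone geometry with new payload
with_data <- function(v, data, units = v$units) {
  volume_grid(data, spacing = v$spacing, origin = v$origin, units = units)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) stop("volumes do not share grid geometry")
  invisible(TRUE)
}

#' Convert between voxel indices and world (mm) coordinates
#'
#' @param v a `volume_grid`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of mm coordinates (or indices for the inverse).
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx - 1, 2L, v$spacing, "*"), 2L, v$origin, "+")
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of mm coordinates.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  sweep(sweep(xyz, 2L, v$origin, "-"), 2L, v$spacing, "/") + 1
}

#' Integer-coded tissue label map
#'
#' A `tissue_label_map` is a `volume_grid` whose data are integer tissue codes
#' with an attached code table. The default code table is the brain set used
#' throughout: 0 background/air, 1 gray matter, 2 white matter, 3 CSF.
#'
#' @param labels integer 3D array.
#' @param spacing,origin grid geometry, as in [volume_grid()].
#' @param code_table named integer vector mapping tissue names to codes.
#' @return object of class `c("tissue_label_map", "volume_grid")`.
#' @export
tissue_label_map <- function(labels, spacing, origin = c(0, 0, 0),
                             code_table = default_code_table()) {
  storage.mode(labels) <- "integer"
  v <- volume_grid(labels, spacing, origin, units = "label")
  v$code_table <- code_table
  class(v) <- c("tissue_label_map", "volume_grid")
  present <- unique(as.vector(labels))
  if (!all(present %in% code_table))
    stop("label values not in code_table: ",
         paste(setdiff(present, code_table), collapse = ", "))
  v
}

#' @rdname tissue_label_map
#' @export
default_code_table <- function() {
  c(background = 0L, gm = 1L, wm = 2L, csf = 3L)
}

#' @rdname tissue_label_map
#' @param v a `tissue_label_map` (or any volume: nonzero voxels are foreground).
#' @export
foreground_mask <- function(v) {
  if (inherits(v, "tissue_label_map")) v$data != 0L else v$data != 0
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Single-frame 4D payloads are squeezed to 3D. A complex volume previously
#' written by [write_volume()] (magnitude/phase pair plus JSON sidecar) is
#' reconstructed transparently when `path` points at the sidecar's base name.
#'
#' @param path file path to a `.nii`/`.nii.gz` volume.
#' @param expected_units unit tag to attach to the result.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path, expected_units = "") {
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(path) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (isTRUE(meta$complex)) {
      mag <- read_volume(file.path(dirname(sidecar), meta$magnitude))
      ph <- read_volume(file.path(dirname(sidecar), meta$phase))
      return(with_data(mag, mag$data * exp(1i * ph$data),
                       units = expected_units))
    }
  }
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D (or single-frame 4D) volume, got ",
         length(d), " dimensions")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  pd <- abs(pd[seq_len(3L)])
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel spacing in ", path)
  # our convention is axis-aligned: take the xform translation as the origin
  # when the rotation part is diagonal, else fall back to zero
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- c(0, 0, 0)
  if (!inherits(xf, "try-error")) {
    rot <- xf[1:3, 1:3]
    if (all(abs(rot[row(rot) != col(rot)]) < 1e-4) && all(diag(rot) > 0))
      orig <- as.numeric(xf[1:3, 4])
  }
  volume_grid(array(as.numeric(img), dim = d), spacing = pd,
              origin = orig, units = expected_units)
}

#' Write a volume to NIfTI-1
#'
#' Real volumes are written as a single file. Complex volumes are stored as a
#' magnitude/phase pair (`<base>_mag.nii`, `<base>_phase.nii`) with a JSON
#' sidecar `<base>.json` recording the pairing; [read_volume()] reassembles
#' them.
#'
#' @param v a `volume_grid`.
#' @param path destination path (`.nii`).
#' @return invisibly, the paths written.
#' @export
write_volume <- function(v, path) {
  validate_volume_grid(v)
  if (is.complex(v$data)) {
    base <- sub("\\.nii(\\.gz)?$", "", path)
    mag_p <- paste0(base, "_mag.nii")
    ph_p <- paste0(base, "_phase.nii")
    write_volume(with_data(v, Mod(v$data), units = v$units), mag_p)
    write_volume(with_data(v, Arg(v$data), units = "rad"), ph_p)
    jsonlite::write_json(
      list(complex = TRUE, magnitude = basename(mag_p),
           phase = basename(ph_p), units = v$units),
      paste0(base, ".json"), auto_unbox = TRUE)
    return(invisible(c(mag_p, ph_p, paste0(base, ".json"))))
  }
  dat <- v$data
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(c(v$spacing, 1))
  m[1:3, 4] <- v$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  ok <- try(suppressWarnings(RNifti::writeNifti(img, path)), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path))
    stop("cannot write volume to ", path)
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Maps every reference voxel centre to its world coordinate, evaluates the
#' moving volume there (trilinear interpolation in physical space, or nearest
#' neighbour — mandatory for label maps), and fills voxels outside the moving
#' volume's support with 0 (background). Grids must be axis-aligned in the
#' shared world frame; no rotation is applied.
#'
#' @param moving the `volume_grid` to resample.
#' @param reference `volume_grid` (or `tissue_label_map`) supplying the target
#'   geometry.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return a `volume_grid` with the reference geometry.
#' @export
resample_to_reference <- function(moving, reference,
                                  mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  dm <- dim(moving$data)
  dr <- dim(reference$data)
  idx <- as.matrix(expand.grid(i = seq_len(dr[1]), j = seq_len(dr[2]),
                               k = seq_len(dr[3])))
  w <- voxel_to_world(reference, idx)
  ci <- world_to_voxel(moving, w)   # fractional 1-based indices in moving
  inside <- ci[, 1] >= 1 & ci[, 1] <= dm[1] &
    ci[, 2] >= 1 & ci[, 2] <= dm[2] &
    ci[, 3] >= 1 & ci[, 3] <= dm[3]
  if (!any(inside))
    stop("empty overlap: the moving volume's physical extent does not ",
         "intersect the reference grid")
  out <- array(if (is.complex(moving$data)) 0i else 0, dim = dr)
  ci_in <- ci[inside, , drop = FALSE]
  if (mode == "nearest") {
    ni <- round(ci_in)
    vals <- moving$data[cbind(ni[, 1], ni[, 2], ni[, 3])]
  } else {
    f <- pmin(floor(ci_in), rep(dm - 1L, each = nrow(ci_in)))
    f <- pmax(f, 1)
    t <- ci_in - f
    vals <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) t[, 1] else 1 - t[, 1]) *
        (if (dy) t[, 2] else 1 - t[, 2]) *
        (if (dz) t[, 3] else 1 - t[, 3])
      vals <- vals + wt * moving$data[cbind(f[, 1] + dx, f[, 2] + dy,
                                            f[, 3] + dz)]
    }
  }
  out[inside] <- vals
  res <- volume_grid(out, spacing = reference$spacing,
                     origin = reference$origin, units = moving$units)
  if (inherits(moving, "tissue_label_map")) {
    if (mode != "nearest")
      stop("label maps must be resampled with mode = 'nearest'")
    res <- tissue_label_map(array(as.integer(out), dim = dr),
                            spacing = reference$spacing,
                            origin = reference$origin,
                            code_table = moving$code_table)
  }
  res
}

#' Region-interior mask by Euclidean erosion
#'
#' Selects voxels whose entire spherical neighbourhood of radius `margin`
#' (in voxel units, clipped at the volume edge) shares the voxel's label.
#' Used to restrict recovery statistics to voxels unaffected by the
#' boundary behaviour of neighbourhood filters: a margin of two kernel
#' half-widths keeps every footprint the filter sees fully inside one
#' region.
#'
#' @param labels a `tissue_label_map`.
#' @param margin erosion radius in voxels.
#' @return logical array over the grid; background is always `FALSE`.
#' @export
region_interior_mask <- function(labels, margin) {
  lab <- labels$data
  d <- dim(lab)
  keep <- array(TRUE, dim = d)
  off <- as.matrix(expand.grid(x = -margin:margin, y = -margin:margin,
                               z = -margin:margin))
  off <- off[rowSums(off^2) <= margin^2 & rowSums(abs(off)) > 0, ,
             drop = FALSE]
  for (r in seq_len(nrow(off))) {
    dx <- off[r, 1]; dy <- off[r, 2]; dz <- off[r, 3]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    same <- lab[xs, ys, zs, drop = FALSE] ==
      lab[xs + dx, ys + dy, zs + dz, drop = FALSE]
    keep[xs, ys, zs] <- keep[xs, ys, zs, drop = FALSE] & same
  }
  keep & lab != 0L
}
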