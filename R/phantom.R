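#' Specification of a digital conductivity phantom
#'
#' Three phantom families are supported, mirroring the objects used to
#' validate the imaging pipeline: `"sphere"` (a homogeneous sphere mimicking
#' distilled water, sigma 0.01 S/m, eps_r 80), `"vials6"` (six saline vials
#' at 0.16-0.75 S/m inside a water-filled cylindrical container), and
#' `"brainlike"` (nested GM / WM / CSF compartments with ventricles). The
#' default output grid is 128 x 128 x 35 voxels at (2.3, 2.3, 2.5) mm, the
#' acquisition grid of the phase sequence the pipeline targets.
#'
#' @param kind phantom family.
#' @param shape length-3 integer grid size.
#' @param spacing length-3 voxel size in mm.
#' @param sigma per-region conductivities in S/m (region order is
#'   kind-specific; see Details).
#' @param eps_r per-region relative permittivities.
#' @param geometry named list of geometry parameters in mm (radii, centres);
#'   kind-specific defaults are filled in.
#' @param noise_sd_phase additive Gaussian phase noise SD in rad.
#' @param noise_sd_magnitude relative Gaussian noise SD on the B1+ magnitude.
#' @param b1_amplitude peak B1+ magnitude in tesla (default 5 uT, a typical
#'   3T volume-coil transmit amplitude); sets the absolute SAR scale.
#' @param seed integer RNG seed making the phantom a pure function of its spec.
#' @details For `"vials6"` the regions are vials 1-6 then the container
#'   water; for `"sphere"` the single sphere; for `"brainlike"` GM, WM, CSF.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("vials6", "sphere", "brainlike"),
                         shape = c(128L, 128L, 35L),
                         spacing = c(2.3, 2.3, 2.5),
                         sigma = NULL, eps_r = NULL, geometry = list(),
                         noise_sd_phase = 0.01, noise_sd_magnitude = 0.01,
                         b1_amplitude = 5e-6, seed = 1234L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    vials6 = list(
      sigma = c(0.16, 0.32, 0.39, 0.46, 0.56, 0.75, 0.01),
      eps_r = c(rep(78, 6), 80),
      geometry = list(container_radius = 55, vial_radius = 14,
                      ring_radius = 32)),
    sphere = list(sigma = 0.01, eps_r = 80,
                  geometry = list(radius = 80)),
    brainlike = list(
      sigma = c(gm = 0.59, wm = 0.34, csf = 2.14),
      eps_r = c(gm = 73.5, wm = 52.5, csf = 84.0),
      geometry = list(head_semiaxes = c(85, 105, 40),
                      csf_thickness = 6, gm_thickness = 14,
                      ventricle_semiaxes = c(10, 22, 10),
                      ventricle_offset = 14)))
  spec <- structure(list(
    kind = kind, shape = as.integer(shape), spacing = as.numeric(spacing),
    sigma = sigma %||% defaults$sigma,
    eps_r = eps_r %||% defaults$eps_r,
    geometry = utils::modifyList(defaults$geometry, geometry),
    noise_sd_phase = noise_sd_phase,
    noise_sd_magnitude = noise_sd_magnitude,
    b1_amplitude = b1_amplitude,
    seed = as.integer(seed)), class = "phantom_spec")
  if (any(spec$sigma < 0)) stop("conductivities must be >= 0")
  if (noise_sd_phase < 0 || noise_sd_magnitude < 0)
    stop("noise SDs must be >= 0")
  spec
}

# world coordinates of all voxel centres, grid centred on the origin
phantom_coords <- function(shape, spacing) {
  ctr <- (shape - 1) / 2 * spacing
  list(x = (seq_len(shape[1]) - 1) * spacing[1] - ctr[1],
       y = (seq_len(shape[2]) - 1) * spacing[2] - ctr[2],
       z = (seq_len(shape[3]) - 1) * spacing[3] - ctr[3])
}

#' Build the label map and true property volumes of a phantom
#'
#' Regions are disjoint by construction (later regions never overwrite
#' earlier ones). The conductivity and permittivity maps are piecewise
#' constant at the per-region values; a `reference` volume with distinct
#' per-region intensities (an anatomical-contrast stand-in) is returned for
#' filter adaptation.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `labels` (a [tissue_label_map()]), `sigma`,
#'   `eps_r` and `reference` (each a [volume_grid()]), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  co <- phantom_coords(sh, spec$spacing)
  X <- array(co$x, dim = sh)
  Y <- array(rep(co$y, each = sh[1]), dim = sh)
  Z <- array(rep(co$z, each = sh[1] * sh[2]), dim = sh)
  lab <- array(0L, dim = sh)
  g <- spec$geometry
  if (spec$kind == "vials6") {
    r2xy <- X^2 + Y^2
    lab[r2xy <= g$container_radius^2] <- 7L   # container water
    ang <- (0:5) * pi / 3
    for (v in 1:6) {
      cx <- g$ring_radius * cos(ang[v]); cy <- g$ring_radius * sin(ang[v])
      lab[(X - cx)^2 + (Y - cy)^2 <= g$vial_radius^2] <- v
    }
    code_table <- c(background = 0L, vial1 = 1L, vial2 = 2L, vial3 = 3L,
                    vial4 = 4L, vial5 = 5L, vial6 = 6L, water = 7L)
    region_codes <- 1:7
    # anatomical-contrast model: saline vials image alike but contrast
    # strongly against the distilled-water bath (as in bSSFP/T1 images);
    # only spatially adjacent structures need separated intensities
    ref_intensity <- c(seq(0.6, 1.0, length.out = 6), 0.15)
  } else if (spec$kind == "sphere") {
    lab[X^2 + Y^2 + Z^2 <= g$radius^2] <- 1L
    code_table <- c(background = 0L, sphere = 1L)
    region_codes <- 1L
    ref_intensity <- 1
  } else {   # brainlike
    hs <- g$head_semiaxes
    inside <- function(s) (X / s[1])^2 + (Y / s[2])^2 + (Z / s[3])^2 <= 1
    lab[inside(hs)] <- 3L                                  # outer CSF
    lab[inside(hs - g$csf_thickness)] <- 1L                # GM shell
    lab[inside(hs - g$csf_thickness - g$gm_thickness)] <- 2L  # WM core
    vs <- g$ventricle_semiaxes
    for (s in c(-1, 1)) {
      v <- ((X - s * g$ventricle_offset) / vs[1])^2 +
        (Y / vs[2])^2 + (Z / vs[3])^2 <= 1
      lab[v] <- 3L                                         # ventricles
    }
    code_table <- default_code_table()
    region_codes <- 1:3
    # T1-like contrast: WM bright, GM intermediate, CSF dark
    ref_intensity <- c(0.6, 1.0, 0.2)
  }
  sig <- array(0, dim = sh)
  eps <- array(0, dim = sh)
  ref <- array(0, dim = sh)
  for (i in seq_along(region_codes)) {
    m <- lab == region_codes[i]
    sig[m] <- spec$sigma[i]
    eps[m] <- spec$eps_r[i]
    ref[m] <- ref_intensity[i]
  }
  mk <- function(a, u) volume_grid(a, spec$spacing, origin = c(0, 0, 0),
                                   units = u)
  list(labels = tissue_label_map(lab, spec$spacing, code_table = code_table),
       sigma = mk(sig, "S/m"), eps_r = mk(eps, ""),
       reference = mk(ref, "a.u."), spec = spec)
}

#' Forward transceive phase consistent with the Helmholtz relation
#'
#' Inside each homogeneous region the generated phase is the quadratic bowl
#' `phi(r) = (mu0*omega*sigma/3) * |r - c|^2` about the region centroid `c`,
#' whose analytic Laplacian is `2*mu0*omega*sigma` at every interior voxel —
#' exactly the relation the phase-based Helmholtz-EPT inverse assumes. Phase
#' continuity across region boundaries is deliberately not enforced; boundary
#' voxels are where any Helmholtz reconstruction is known to break down and
#' are excluded from recovery statements.
#'
#' @param sigma_map `volume_grid` of conductivity (S/m), piecewise constant.
#' @param cfg a [physics_config()].
#' @param labels optional `tissue_label_map` defining the regions; when
#'   absent, regions are taken as the level sets of `sigma_map`.
#' @return phase `volume_grid` in rad (0 over background).
#' @export
forward_transceive_phase <- function(sigma_map, cfg = physics_config(),
                                     labels = NULL) {
  if (any(sigma_map$data < 0)) stop("sigma must be >= 0 everywhere")
  sh <- dim(sigma_map$data)
  reg <- if (is.null(labels)) {
    match(as.vector(sigma_map$data), unique(as.vector(sigma_map$data)))
  } else {
    stop_if_geometry_differs(sigma_map, labels)
    as.vector(labels$data) + 1L
  }
  fg <- if (is.null(labels)) as.vector(sigma_map$data) != 0 else
    as.vector(labels$data) != 0L
  co <- phantom_coords(sh, sigma_map$spacing)
  xyz_mm <- cbind(rep(co$x, times = sh[2] * sh[3]),
                  rep(rep(co$y, each = sh[1]), times = sh[3]),
                  rep(co$z, each = sh[1] * sh[2]))
  phase <- numeric(prod(sh))
  for (r in unique(reg[fg])) {
    m <- reg == r & fg
    ctr <- colMeans(xyz_mm[m, , drop = FALSE])
    d2 <- rowSums(sweep(xyz_mm[m, , drop = FALSE], 2L, ctr)^2) * 1e-6  # m^2
    a <- cfg$mu0 * cfg$omega * sigma_map$data[which(m)[1]] / 3
    phase[m] <- a * d2
  }
  with_data(sigma_map, array(phase, dim = sh), units = "rad")
}

#' Synthetic B1+ magnitude field
#'
#' A stand-in for the quadrature birdcage transmit magnitude: either uniform
#' over the foreground or a smooth centre-bright, radially decaying profile
#' (`amplitude * (1 - 0.3 * (d/dmax)^2)` with `d` the distance to the
#' foreground centroid), which has continuous second derivatives and is
#' strictly positive and monotone non-increasing along rays.
#'
#' @param labels a [tissue_label_map()] defining the foreground.
#' @param model `"uniform"` or `"radial-smooth"`.
#' @param amplitude peak magnitude in arbitrary units; 0 is rejected as it
#'   would make the downstream E-field identically zero.
#' @return magnitude `volume_grid` (a.u.), 0 over background.
#' @export
forward_b1_magnitude <- function(labels, model = c("radial-smooth", "uniform"),
                                 amplitude = 1) {
  model <- match.arg(model)
  if (amplitude == 0)
    stop("amplitude 0 yields an all-zero B1+ map, invalid for E-field use")
  sh <- dim(labels$data)
  fg <- foreground_mask(labels)
  out <- array(0, dim = sh)
  if (model == "uniform") {
    out[fg] <- amplitude
  } else {
    co <- phantom_coords(sh, labels$spacing)
    X <- array(co$x, dim = sh)
    Y <- array(rep(co$y, each = sh[1]), dim = sh)
    Z <- array(rep(co$z, each = sh[1] * sh[2]), dim = sh)
    ctr <- c(mean(X[fg]), mean(Y[fg]), mean(Z[fg]))
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
    dmax2 <- max(d2[fg])
    prof <- amplitude * (1 - 0.3 * d2 / dmax2)
    out[fg] <- prof[fg]
  }
  volume_grid(out, labels$spacing, origin = labels$origin, units = "a.u.")
}

#' Add reproducible Gaussian noise to a volume
#'
#' @param v a `volume_grid`.
#' @param sd noise SD in the units of `v`.
#' @param seed integer seed; the same seed always yields the same volume.
#' @return `volume_grid` of the same geometry.
#' @export
add_noise <- function(v, sd, seed = 1234L) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(v)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  with_data(v, v$data + array(stats::rnorm(length(v$data), sd = sd),
                              dim = dim(v$data)))
}

#' Generate a complete noisy phantom input set
#'
#' Convenience wrapper: builds the phantom, its forward-consistent transceive
#' phase and B1+ magnitude, and applies the spec's noise with its seed
#' (phase noise seed `seed`, magnitude noise seed `seed + 1`).
#'
#' @param spec a [phantom_spec()].
#' @param cfg a [physics_config()].
#' @return list with `labels`, `sigma`, `eps_r`, `reference`, `phase`,
#'   `b1_magnitude`, and the noiseless `phase_true`.
#' @export
generate_phantom_inputs <- function(spec, cfg = physics_config()) {
  ph <- make_phantom(spec)
  phase_true <- forward_transceive_phase(ph$sigma, cfg, labels = ph$labels)
  b1 <- forward_b1_magnitude(ph$labels, model = "radial-smooth",
                             amplitude = spec$b1_amplitude)
  b1$units <- "T"
  phase <- add_noise(phase_true, spec$noise_sd_phase, seed = spec$seed)
  if (spec$noise_sd_magnitude > 0) {
    fg <- foreground_mask(ph$labels)
    scale_sd <- spec$noise_sd_magnitude * mean(b1$data[fg])
    b1 <- add_noise(b1, scale_sd, seed = spec$seed + 1L)
    b1$data[!fg] <- 0
    b1$data[fg] <- pmax(b1$data[fg], 0)
  }
  c(ph[c("labels", "sigma", "eps_r", "reference")],
    list(phase = phase, b1_magnitude = b1, phase_true = phase_true,
         spec = spec))
}
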