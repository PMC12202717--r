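#' Physical constants for the RF field computations
#'
#' Houses the angular Larmor frequency, vacuum permeability and permittivity,
#' mass density, and the time-harmonic sign convention. `omega` is always
#' derived as `2*pi*f0` and cannot be set independently.
#'
#' @param f0 RF frequency in Hz (default 128 MHz, the 3T Larmor frequency).
#' @param mu0 vacuum permeability in H/m.
#' @param eps0 vacuum permittivity in F/m.
#' @param rho tissue mass density in kg/m^3 (default 1000).
#' @param time_convention `"+iwt"` or `"-iwt"`; fixes the sign of the
#'   imaginary part of the complex admittance `sigma + i*omega*eps`. The
#'   magnitude of E, and hence SAR, is invariant to the choice.
#' @return object of class `physics_config`.
#' @export
physics_config <- function(f0 = 128e6, mu0 = 4e-7 * pi,
                           eps0 = 8.8541878128e-12, rho = 1000,
                           time_convention = c("+iwt", "-iwt")) {
  time_convention <- match.arg(time_convention)
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive")
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  if (!is.finite(mu0) || mu0 <= 0) stop("mu0 must be positive")
  structure(list(f0 = f0, omega = 2 * pi * f0, mu0 = mu0, eps0 = eps0,
                 rho = rho, time_convention = time_convention),
            class = "physics_config")
}

#' Literature electrical properties per tissue
#'
#' Conductivity and relative permittivity at the working frequency for each
#' tissue code. The shipped defaults are the standard low-frequency
#' dielectric database values at 128 MHz: sigma 0.59 / 0.34 / 2.14 S/m and
#' eps_r 73.5 / 52.5 / 84.0 for gray matter / white matter / CSF.
#'
#' @param tissue,code,sigma,eps_r parallel vectors defining the table.
#' @return data.frame of class `electrical_properties_table`.
#' @export
electrical_properties_table <- function(tissue = c("gm", "wm", "csf"),
                                        code = c(1L, 2L, 3L),
                                        sigma = c(0.59, 0.34, 2.14),
                                        eps_r = c(73.5, 52.5, 84.0)) {
  tab <- data.frame(tissue = tissue, code = as.integer(code),
                    sigma = sigma, eps_r = eps_r,
                    stringsAsFactors = FALSE)
  if (any(tab$sigma < 0)) stop("conductivity must be >= 0 for every tissue")
  if (any(tab$eps_r < 1)) stop("relative permittivity must be >= 1")
  if (anyDuplicated(tab$code)) stop("duplicate tissue codes")
  class(tab) <- c("electrical_properties_table", "data.frame")
  tab
}

#' Tissue-specific SAR correction factors
#'
#' Multiplicative factors repairing the systematic SAR underestimation that
#' follows from using only the measurable B1+ component (neglecting B1- and
#' B1z). Defaults: pointwise SAR 3.08 / 1.79 / 2.59 and 10-g SAR
#' 2.11 / 2.06 / 1.95 for gray matter / white matter / CSF.
#'
#' @param tissue,code,sar_factor,sar10g_factor parallel vectors.
#' @return data.frame of class `correction_factor_table`.
#' @export
correction_factor_table <- function(tissue = c("gm", "wm", "csf"),
                                    code = c(1L, 2L, 3L),
                                    sar_factor = c(3.08, 1.79, 2.59),
                                    sar10g_factor = c(2.11, 2.06, 1.95)) {
  tab <- data.frame(tissue = tissue, code = as.integer(code),
                    sar_factor = sar_factor, sar10g_factor = sar10g_factor,
                    stringsAsFactors = FALSE)
  if (any(tab$sar_factor < 1) || any(tab$sar10g_factor < 1))
    stop("correction factors must be >= 1")
  class(tab) <- c("correction_factor_table", "data.frame")
  tab
}

#' Default filter parameters
#'
#' The Savitzky-Golay kernels and postprocessing settings of the standard
#' workflow: cuboid size 5 (degree 2, anatomical weight 0.05) for the phase
#' Laplacian; cube size 10, weight 0.1 for the conductivity postprocess;
#' ellipsoid size 4 for the B1+ derivatives; Gaussian sigma 0.4 voxels and
#' the mean + 9 SD outlier threshold on the SAR map.
#'
#' @return named list of filter parameter groups.
#' @export
default_filter_params <- function() {
  list(
    ept = list(shape = "cuboid", size = 5L, degree = 2L, weight = 0.05),
    postprocess = list(shape = "cube", size = 10L, weight = 0.1),
    efield = list(shape = "ellipsoid", size = 4L, degree = 2L, weight = 0.05),
    gaussian_sigma = 0.4,      # voxels
    outlier_k = 9
  )
}

#' Full effective pipeline configuration
#'
#' @param physics a [physics_config()].
#' @param tissues an [electrical_properties_table()].
#' @param correction a [correction_factor_table()].
#' @param filters filter parameter list, see [default_filter_params()].
#' @param pipeline free-form pipeline section (input paths or a phantom spec).
#' @return list of class `imsar_config`.
#' @export
default_config <- function(physics = physics_config(),
                           tissues = electrical_properties_table(),
                           correction = correction_factor_table(),
                           filters = default_filter_params(),
                           pipeline = list()) {
  structure(list(physics = physics, tissues = tissues,
                 correction = correction, filters = filters,
                 pipeline = pipeline),
            class = "imsar_config")
}

#' Load (or build) the effective configuration from a YAML file
#'
#' Absent keys fall back to the documented defaults, so an empty document
#' yields the full standard configuration (128 MHz, 1000 kg/m^3, the default
#' factor tables and filter parameters). `omega` is always recomputed from
#' `f0`.
#'
#' @param path YAML config file, or `NULL` for pure defaults.
#' @return list of class `imsar_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ph <- raw$physics
  physics <- physics_config(
    f0 = ph$f0 %||% 128e6,
    mu0 = ph$mu0 %||% (4e-7 * pi),
    eps0 = ph$eps0 %||% 8.8541878128e-12,
    rho = ph$rho %||% 1000,
    time_convention = ph$time_convention %||% "+iwt")
  tissues <- if (is.null(raw$tissues)) electrical_properties_table() else {
    tt <- raw$tissues
    electrical_properties_table(
      tissue = vapply(tt, `[[`, "", "tissue"),
      code = vapply(tt, `[[`, 0L, "code"),
      sigma = vapply(tt, `[[`, 0, "sigma"),
      eps_r = vapply(tt, `[[`, 0, "eps_r"))
  }
  correction <- if (is.null(raw$correction)) correction_factor_table() else {
    ct <- raw$correction
    correction_factor_table(
      tissue = vapply(ct, `[[`, "", "tissue"),
      code = vapply(ct, `[[`, 0L, "code"),
      sar_factor = vapply(ct, `[[`, 0, "sar_factor"),
      sar10g_factor = vapply(ct, `[[`, 0, "sar10g_factor"))
  }
  filters <- utils::modifyList(default_filter_params(), raw$filters %||% list())
  default_config(physics = physics, tissues = tissues,
                 correction = correction, filters = filters,
                 pipeline = raw$pipeline %||% list())
}

#' Serialize the effective configuration to YAML
#'
#' Reloading the written file with [load_config()] reproduces the
#' configuration exactly.
#'
#' @param cfg an `imsar_config`.
#' @param path destination YAML path.
#' @export
write_config <- function(cfg, path) {
  to_rows <- function(df) lapply(seq_len(nrow(df)), function(i)
    as.list(df[i, , drop = FALSE]))
  doc <- list(
    physics = cfg$physics[c("f0", "mu0", "eps0", "rho", "time_convention")],
    tissues = to_rows(cfg$tissues),
    correction = to_rows(cfg$correction),
    filters = cfg$filters,
    pipeline = cfg$pipeline)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
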