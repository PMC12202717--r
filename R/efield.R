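#' Assemble the complex B1+ field from magnitude and transceive phase
#'
#' Under the transceive phase assumption the measured phase of a suitable
#' sequence is twice the transmit phase, so the complex transmit field is
#' `b1plus = magnitude * exp(i * phi_tr / 2)`.
#'
#' @param magnitude B1+ magnitude `volume_grid` (a.u. or tesla), values >= 0.
#' @param transceive_phase phase `volume_grid` in rad, same geometry.
#' @return complex `volume_grid` of class `c("complex_b1_map",
#'   "volume_grid")` with a `provenance` field naming the two sources.
#' @export
assemble_b1plus <- function(magnitude, transceive_phase) {
  stop_if_geometry_differs(magnitude, transceive_phase)
  if (any(magnitude$data < 0, na.rm = TRUE))
    stop("B1+ magnitude must be non-negative")
  b1 <- with_data(magnitude,
                  magnitude$data * exp(1i * transceive_phase$data / 2),
                  units = magnitude$units)
  b1$provenance <- list(magnitude_units = magnitude$units,
                        phase_units = transceive_phase$units)
  class(b1) <- c("complex_b1_map", "volume_grid")
  b1
}

#' Approximate the E-field from B1+ via Ampere's law
#'
#' MRI measures only the positively rotating transmit component B1+; the
#' unmeasurable B1- and Bz are closed out as zero, giving `Bx = B1+`,
#' `By = -i*B1+`, `Bz = 0`. The time-harmonic Ampere-Maxwell law
#' `curl(B/mu0) = (sigma + i*omega*eps) * E` then yields per voxel
#' \deqn{E_x = i \partial_z B_1^+ / (\mu_0 y),\quad
#'       E_y = \partial_z B_1^+ / (\mu_0 y),\quad
#'       E_z = (-i \partial_x B_1^+ - \partial_y B_1^+) / (\mu_0 y)}
#' with `y = sigma + i*omega*eps0*eps_r` the complex admittance (sign of the
#' imaginary part set by the time convention; |E| is invariant to it). The
#' derivatives are anatomically adapted Savitzky-Golay first derivatives.
#' This closure systematically underestimates |E|; the tissue-specific SAR
#' correction factors repair that bias downstream.
#'
#' @param b1 a `complex_b1_map` from [assemble_b1plus()].
#' @param sigma conductivity `volume_grid` (S/m), typically the
#'   piecewise-constant tissue map.
#' @param eps_table an [electrical_properties_table()] supplying per-tissue
#'   relative permittivity, expanded over `labels`.
#' @param labels a `tissue_label_map`.
#' @param cfg a [physics_config()].
#' @param kernel degree-2 [sg_kernel()] for the derivatives (default:
#'   ellipsoid, semi-axis 4, anatomical weight 0.05).
#' @param reference optional reference `volume_grid` for adaptation; the
#'   label map itself is used when absent.
#' @return list of class `efield_map` with complex `volume_grid`s `Ex`,
#'   `Ey`, `Ez` (background voxels 0) and the admittance used.
#' @export
efield_from_b1plus <- function(b1, sigma, eps_table, labels,
                               cfg = physics_config(),
                               kernel = sg_kernel("ellipsoid", 4L,
                                                  weight = 0.05),
                               reference = NULL) {
  stop_if_geometry_differs(b1, sigma)
  stop_if_geometry_differs(b1, labels)
  fg <- foreground_mask(labels)
  eps_r <- expand_property(labels, eps_table, "eps_r")
  sgn <- if (cfg$time_convention == "+iwt") 1 else -1
  adm <- sigma$data + sgn * 1i * cfg$omega * cfg$eps0 * eps_r
  if (any(fg & adm == 0))
    stop("zero admittance at a foreground voxel")
  if (is.null(reference))
    reference <- with_data(sigma, array(as.numeric(labels$data),
                                        dim = dim(labels$data)), units = "")
  gr <- sg_gradient(b1, kernel, labels = labels, reference = reference)
  dx <- gr$ddx$data; dy <- gr$ddy$data; dz <- gr$ddz$data
  den <- cfg$mu0 * adm
  mkE <- function(num) {
    e <- num / den
    e[!fg] <- 0
    with_data(sigma, e, units = "V/m")
  }
  res <- list(Ex = mkE(1i * dz), Ey = mkE(dz), Ez = mkE(-1i * dx - dy),
              admittance = with_data(sigma, adm, units = ""))
  class(res) <- "efield_map"
  res
}

# expand a per-tissue property column over a label map (background 0)
expand_property <- function(labels, table, column) {
  out <- array(0, dim = dim(labels$data))
  for (i in seq_len(nrow(table))) {
    m <- labels$data == table$code[i]
    out[m] <- table[[column]][i]
  }
  present <- setdiff(unique(as.vector(labels$data)), 0L)
  missing <- setdiff(present, table$code)
  if (length(missing))
    stop("no electrical properties for tissue code(s): ",
         paste(missing, collapse = ", "))
  out
}

#' Squared E-field magnitude
#'
#' @param E an `efield_map`.
#' @return `volume_grid` of `|Ex|^2 + |Ey|^2 + |Ez|^2` (V^2/m^2).
#' @export
efield_magnitude2 <- function(E) {
  m2 <- Mod(E$Ex$data)^2 + Mod(E$Ey$data)^2 + Mod(E$Ez$data)^2
  with_data(E$Ex, m2, units = "V^2/m^2")
}
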