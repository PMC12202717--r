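#' Phase-based Helmholtz-EPT conductivity reconstruction
#'
#' Under the transceive phase assumption (measured phase approximately twice
#' the transmit phase) and locally homogeneous electrical properties, the
#' conductivity follows from the transceive phase alone:
#' `sigma = laplacian(phi_tr) / (2 * mu0 * omega)`. The Laplacian is
#' evaluated with an (optionally anatomically adapted) 3D Savitzky-Golay
#' filter. Negative values are retained, not clipped: they flag voxels where
#' the local-homogeneity assumption failed and are excluded later from
#' per-tissue means.
#'
#' @param phase transceive phase `volume_grid` in rad.
#' @param kernel degree-2 [sg_kernel()] (default: cuboid size 5, anatomical
#'   weight 0.05).
#' @param cfg a [physics_config()].
#' @param labels optional `tissue_label_map` foreground.
#' @param reference optional anatomical reference `volume_grid` for filter
#'   adaptation.
#' @return conductivity `volume_grid` in S/m; unreconstructable voxels `NA`.
#' @export
conductivity_from_phase <- function(phase,
                                    kernel = sg_kernel("cuboid", 5L,
                                                       weight = 0.05),
                                    cfg = physics_config(), labels = NULL,
                                    reference = NULL) {
  lap <- sg_laplacian(phase, kernel, labels = labels, reference = reference)
  with_data(lap, lap$data / (2 * cfg$mu0 * cfg$omega), units = "S/m")
}

#' Reference-adapted postprocessing filter for conductivity maps
#'
#' Replaces each voxel by the weight-normalised, reference-adapted weighted
#' mean of the conductivity over a cubic footprint (default cube size 10,
#' weight 0.1). With a tissue-contrasted reference this smooths within
#' tissues while blocking cross-boundary mixing. The output at each voxel
#' lies within the range of the input over its footprint.
#'
#' @param sigma conductivity `volume_grid` (S/m).
#' @param reference anatomical reference `volume_grid` (same geometry).
#' @param kernel an [sg_kernel()]; its `weight` drives the adaptation.
#' @param labels optional `tissue_label_map` foreground.
#' @return filtered conductivity `volume_grid`.
#' @export
ept_postprocess <- function(sigma, reference,
                            kernel = sg_kernel("cube", 10L, weight = 0.1),
                            labels = NULL) {
  stop_if_geometry_differs(sigma, reference)
  out <- sg_weighted_mean(sigma, kernel, labels = labels,
                          reference = reference)
  out$units <- sigma$units
  out
}

#' Piecewise-constant conductivity by tissue averaging
#'
#' Every voxel of tissue `t` is assigned the mean reconstructed conductivity
#' over `t`, the noise-reduction step that precedes the E-field computation.
#' Means are taken over reconstructable (non-`NA`), non-negative voxels only;
#' negative reconstructions are artefacts of the homogeneity assumption and
#' would bias the tissue means downward.
#'
#' @param sigma conductivity `volume_grid` (S/m).
#' @param labels a `tissue_label_map` on the same grid.
#' @return list with `volume` (the piecewise-constant `volume_grid`) and
#'   `table` (data.frame: tissue, code, mean, sd, n_voxels).
#' @export
piecewise_mean_conductivity <- function(sigma, labels) {
  stop_if_geometry_differs(sigma, labels)
  codes <- labels$code_table[labels$code_table != 0L]
  present <- intersect(codes, unique(as.vector(labels$data)))
  out <- array(NA_real_, dim = dim(sigma$data))
  out[labels$data == 0L] <- 0
  rows <- lapply(present, function(cd) {
    m <- labels$data == cd
    vals <- sigma$data[m]
    vals <- vals[!is.na(vals) & vals >= 0]
    if (length(vals) == 0L)
      stop("tissue '", names(codes)[match(cd, codes)],
           "' has no reconstructable conductivity voxels")
    out[m] <<- mean(vals)
    data.frame(tissue = names(codes)[match(cd, codes)], code = cd,
               mean = mean(vals), sd = stats::sd(vals),
               n_voxels = length(vals), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(volume = with_data(sigma, out, units = "S/m"), table = tab)
}

#' Full EPT reconstruction chain
#'
#' Convenience wrapper running the standard conductivity workflow: the
#' Savitzky-Golay phase Laplacian with anatomical adaptation, the
#' reference-adapted postprocessing filter, and (optionally) the
#' piecewise-constant tissue averaging.
#'
#' @param phase transceive phase `volume_grid` (rad).
#' @param labels `tissue_label_map` foreground / averaging regions.
#' @param reference anatomical reference for both adaptive filters.
#' @param cfg a [physics_config()].
#' @param filters filter parameter list, see [default_filter_params()].
#' @param piecewise also compute the per-tissue piecewise-constant map?
#' @return list with `sigma_raw`, `sigma_filtered`, and when `piecewise` is
#'   `TRUE` also `sigma_piecewise` and `tissue_table`.
#' @export
reconstruct_conductivity <- function(phase, labels, reference,
                                     cfg = physics_config(),
                                     filters = default_filter_params(),
                                     piecewise = TRUE) {
  k_ept <- sg_kernel(filters$ept$shape, filters$ept$size,
                     degree = filters$ept$degree, weight = filters$ept$weight)
  sigma_raw <- conductivity_from_phase(phase, k_ept, cfg, labels = labels,
                                       reference = reference)
  k_post <- sg_kernel(filters$postprocess$shape, filters$postprocess$size,
                      degree = 2L, weight = filters$postprocess$weight)
  sigma_filtered <- ept_postprocess(sigma_raw, reference, k_post,
                                    labels = labels)
  res <- list(sigma_raw = sigma_raw, sigma_filtered = sigma_filtered)
  if (piecewise) {
    pw <- piecewise_mean_conductivity(sigma_filtered, labels)
    res$sigma_piecewise <- pw$volume
    res$tissue_table <- pw$table
  }
  res
}
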