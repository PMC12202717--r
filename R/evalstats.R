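#' Concentric region partition of a foreground mask
#'
#' Divides the foreground into `center`, `middle` and `outer` shells by
#' normalised radial distance to the foreground centroid (physical mm
#' coordinates), using equal-width thirds of the maximum distance. Used to
#' assess how map agreement varies from the object centre outwards.
#'
#' @param v a `volume_grid` or `tissue_label_map`; nonzero voxels are
#'   foreground.
#' @return integer array over the grid: 0 background, 1 center, 2 middle,
#'   3 outer, with a `levels` attribute naming the codes.
#' @export
region_partition <- function(v) {
  d <- dim(v$data)
  fg <- if (inherits(v, "tissue_label_map")) v$data != 0L else
    (v$data != 0 & !is.na(v$data))
  idx <- which(fg)
  ijk <- arrayInd(idx, d)
  xyz <- voxel_to_world(v, ijk)
  ctr <- colMeans(xyz)
  dist <- sqrt(rowSums(sweep(xyz, 2L, ctr)^2))
  rel <- if (max(dist) > 0) dist / max(dist) else dist
  bin <- pmin(findInterval(rel, c(0, 1 / 3, 2 / 3), rightmost.closed = FALSE),
              3L)
  out <- array(0L, dim = d)
  out[idx] <- bin
  attr(out, "levels") <- c(center = 1L, middle = 2L, outer = 3L)
  out
}

# jointly defined voxel selector shared by all metrics
joint_defined <- function(a, b, region = NULL, partition = NULL) {
  stop_if_geometry_differs(a, b)
  ok <- !is.na(a$data) & !is.na(b$data)
  if (!is.null(region)) {
    if (is.null(partition)) stop("a partition is required to select a region")
    lev <- attr(partition, "levels")
    ok <- ok & (partition == lev[[region]])
  }
  ok
}

#' Mean absolute percentage error between two maps
#'
#' `mean(|a - b| / |b|) * 100` over jointly defined voxels; voxels where the
#' reference `b` is zero are excluded and counted.
#'
#' @param a,b `volume_grid`s on the same grid (`b` is the reference).
#' @param region optional `"center"`, `"middle"` or `"outer"`.
#' @param partition a [region_partition()], required when `region` is given.
#' @return list with `mape` (percent), `n` compared, `n_zero_excluded`.
#' @export
mape <- function(a, b, region = NULL, partition = NULL) {
  ok <- joint_defined(a, b, region, partition)
  nz <- ok & b$data != 0
  list(mape = mean(abs(a$data[nz] - b$data[nz]) / abs(b$data[nz])) * 100,
       n = sum(nz), n_zero_excluded = sum(ok) - sum(nz))
}

#' Pearson correlation between two maps
#'
#' Product-moment correlation over jointly defined voxels with a two-sided
#' test.
#'
#' @inheritParams mape
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(a, b, region = NULL, partition = NULL) {
  ok <- joint_defined(a, b, region, partition)
  ct <- stats::cor.test(a$data[ok], b$data[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Distribution summary of a map
#'
#' Median, interquartile range (linear-interpolation quartiles, type 7),
#' adjusted Fisher-Pearson skewness, minimum and maximum over defined
#' voxels.
#'
#' @param v `volume_grid`.
#' @param labels optional `tissue_label_map` restricting to foreground.
#' @return list with `median`, `iqr`, `skewness`, `min`, `max`, `n`.
#' @export
distribution_summary <- function(v, labels = NULL) {
  fg <- if (is.null(labels)) array(TRUE, dim = dim(v$data)) else
    foreground_mask(labels)
  vals <- v$data[fg & !is.na(v$data)]
  list(median = stats::median(vals),
       iqr = stats::IQR(vals, type = 7),
       skewness = e1071::skewness(vals, type = 2),
       min = min(vals), max = max(vals), n = length(vals))
}

#' Voxelwise 2D co-occurrence histogram of two maps
#'
#' Joint histogram over jointly defined voxels; counts sum to the number of
#' compared voxels. Bin edges are equal-width over each map's range.
#'
#' @inheritParams mape
#' @param bins number of bins per axis.
#' @return list with `counts` (bins x bins matrix, rows = `a` bins),
#'   `a_edges`, `b_edges`, `n`.
#' @export
heatmap2d <- function(a, b, bins = 64L) {
  ok <- joint_defined(a, b)
  av <- a$data[ok]; bv <- b$data[ok]
  a_edges <- seq(min(av), max(av), length.out = bins + 1L)
  b_edges <- seq(min(bv), max(bv), length.out = bins + 1L)
  ai <- pmin(pmax(findInterval(av, a_edges, rightmost.closed = TRUE), 1L), bins)
  bi <- pmin(pmax(findInterval(bv, b_edges, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ai, levels = seq_len(bins)),
               factor(bi, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  list(counts = counts, a_edges = a_edges, b_edges = b_edges, n = sum(ok))
}
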