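#' Fixed-bin-width intensity discretization
#'
#' Quantizes within-mask intensities into levels 1..N with a fixed bin
#' width anchored at the within-mask minimum, the standard precursor to all
#' texture-matrix features.
#'
#' @param volume a [volume3d()].
#' @param mask a `mask3d`; nonzero voxels define the region.
#' @param bin_width positive bin width in intensity units.
#' @return list with `levels` (integer array, 0 outside the mask, 1..N
#'   inside) and `n_levels`.
#' @examples
#' v <- volume3d(array(0:99, c(10, 10, 1)))
#' m <- mask3d(array(1L, c(10, 10, 1)))
#' discretize(v, m, 25)$n_levels  # 4
#' @export
discretize <- function(volume, mask, bin_width) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  check_same_grid(volume, mask)
  inside <- mask$data != 0L
  if (!any(inside)) abort("mask is empty.")
  vals <- volume$data[inside]
  lv <- floor((vals - min(vals)) / bin_width) + 1L
  ## values exactly at the top edge fall in the last bin
  q <- array(0L, dim(volume$data))
  q[inside] <- as.integer(lv)
  list(levels = q, n_levels = max(lv))
}

#' First-order intensity statistics (18 features)
#'
#' IBSI-style first-order features of the within-mask intensity
#' distribution. Entropy and Uniformity use the fixed-bin-width histogram of
#' [discretize()]; Skewness and Kurtosis (excess) of a constant region are
#' defined as 0.
#'
#' @param volume a [volume3d()].
#' @param mask a `mask3d`.
#' @param bin_width bin width for the histogram-based features.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(volume, mask, bin_width = 25) {
  x <- mask_values(volume, mask)
  if (length(x) == 0L) abort("mask is empty.")
  n <- length(x)
  vv <- voxel_volume(volume)
  mu <- mean(x)
  pvar <- mean((x - mu)^2)
  p10 <- quantile(x, 0.1, names = FALSE)
  p90 <- quantile(x, 0.9, names = FALSE)
  mid <- x[x >= p10 & x <= p90]
  sdev <- sqrt(pvar)
  skew <- if (sdev > 1e-12) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (sdev > 1e-12) mean((x - mu)^4) / sdev^4 - 3 else 0
  q <- discretize(volume, mask, bin_width)
  p <- tabulate(q$levels[q$levels > 0L], q$n_levels) / n
  p <- p[p > 0]
  c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = quantile(x, 0.75, names = FALSE) -
      quantile(x, 0.25, names = FALSE),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = if (length(mid)) {
      mean(abs(mid - mean(mid)))
    } else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = pvar,
    Uniformity = sum(p^2)
  )
}

#' Morphological (shape) features (14 features)
#'
#' Shape descriptors of a binary region: volumes, face-based surface area,
#' surface-to-volume ratio, sphericity, maximum 3D and in-plane 2D
#' diameters, and the principal-axis lengths with elongation and flatness.
#' Computed on the original-resolution mask only. A single-voxel region has
#' no meaningful surface; all features are returned as `NA` with a warning.
#'
#' @param mask a `mask3d` (nonzero = region).
#' @param spacing optional spacing override (mm); default the mask's.
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = NULL) {
  if (is.null(spacing)) spacing <- mask$spacing
  m <- mask$data != 0L
  n <- sum(m)
  nm <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
          "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
          "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
          "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
          "Elongation", "Flatness")
  if (n < 2L) {
    warn("region of fewer than 2 voxels: shape features undefined.")
    return(setNames(rep(NA_real_, 14L), nm))
  }
  vox_vol <- n * prod(spacing)

  ## face-based surface area: faces between region and background voxels
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  boundary <- array(FALSE, dim(m))
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    for (s in c(-1L, 1L)) {
      nb <- shift_array(m, s * off, fill = FALSE)
      exposed <- m & !nb
      area <- area + sum(exposed) * face_area[ax]
      boundary <- boundary | exposed
    }
  }
  idx <- which(m, arr.ind = TRUE)
  phys <- sweep(idx - 1, 2, spacing, `*`)
  bidx <- which(boundary & m, arr.ind = TRUE)
  bphys <- sweep(bidx - 1, 2, spacing, `*`)

  max_diam <- sqrt(max_pairwise_dist2(bphys))
  d2_slice <- max_planar_diam2(bidx, spacing, plane = c(1, 2), along = 3)
  d2_col <- max_planar_diam2(bidx, spacing, plane = c(1, 3), along = 2)
  d2_row <- max_planar_diam2(bidx, spacing, plane = c(2, 3), along = 1)

  cv <- stats::cov(phys)
  ev <- sort(pmax(eigen(cv, symmetric = TRUE)$values, 0), decreasing = TRUE)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])

  sphericity <- pi^(1 / 3) * (6 * vox_vol)^(2 / 3) / area
  setNames(c(vox_vol, vox_vol, area, area / vox_vol, sphericity, max_diam,
             sqrt(d2_slice), sqrt(d2_col), sqrt(d2_row), major, minor, least,
             if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
             if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_), nm)
}

## Max squared pairwise distance between rows of a coordinate matrix,
## chunked to bound memory.
max_pairwise_dist2 <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(0)
  if (n > 3000L) {  # thin dense boundaries; extremes survive thinning
    keep <- unique(c(
      seq(1L, n, by = ceiling(n / 3000)),
      apply(xy, 2, which.min), apply(xy, 2, which.max)
    ))
    xy <- xy[keep, , drop = FALSE]
    n <- nrow(xy)
  }
  s2 <- rowSums(xy^2)
  best <- 0
  step <- max(1L, floor(2e6 / n))
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(i0 + step - 1L, n)
    d2 <- outer(s2[ii], s2, `+`) - 2 * xy[ii, , drop = FALSE] %*% t(xy)
    best <- max(best, max(d2))
  }
  best
}

max_planar_diam2 <- function(idx, spacing, plane, along) {
  best <- 0
  for (s in unique(idx[, along])) {
    rows <- idx[idx[, along] == s, plane, drop = FALSE]
    xy <- sweep(rows - 1, 2, spacing[plane], `*`)
    best <- max(best, max_pairwise_dist2(xy))
  }
  best
}
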