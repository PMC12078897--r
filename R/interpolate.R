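## Separable convolution and interpolation helpers shared by the synthetic
## generator, the preprocessing chain and the filter bank.

## Convolve a 3D array with a 1D kernel along one axis, replicate padding.
conv_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    rows <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[k] * m[rows, , drop = FALSE]
  }
  ap[] <- out
  aperm(ap, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (sigma_vox <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## Gaussian smoothing with per-axis sigma in voxels.
gaussian_smooth <- function(a, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0 && dim(a)[ax] > 1L) {
      a <- conv_axis(a, gaussian_kernel_1d(sigma_vox[ax]), ax)
    }
  }
  a
}

## Smooth unit-variance Gaussian random field: white noise smoothed with an
## isotropic Gaussian (sigma in voxels) and rescaled to zero mean, unit sd.
smooth_noise_field <- function(dim3, sigma_vox) {
  z <- array(rnorm(prod(dim3)), dim3)
  if (all(sigma_vox <= 0)) return(z)
  s <- gaussian_smooth(z, sigma_vox)
  sdev <- sd(as.vector(s))
  if (sdev < .Machine$double.eps) return(array(0, dim3))
  (s - mean(s)) / sdev
}

## Trilinear interpolation of array `a` at fractional voxel coordinates
## (1-based). Coordinates are clamped to the grid (replicate padding).
interp_trilinear <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(zi), max(d[3] - 1L, 1L))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

## Nearest-neighbor interpolation at fractional voxel coordinates.
interp_nearest <- function(a, xi, yi, zi) {
  d <- dim(a)
  ix <- pmin(pmax(round(xi), 1), d[1])
  iy <- pmin(pmax(round(yi), 1), d[2])
  iz <- pmin(pmax(round(zi), 1), d[3])
  a[cbind(ix, iy, iz)]
}

## Voxel-coordinate grids (1-based) for a given array dimension.
coord_grids <- function(d) {
  list(
    x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}
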