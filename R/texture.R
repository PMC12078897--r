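## Texture-matrix construction and IBSI-style feature formulas for the five
## families: GLCM, GLRLM, GLSZM, GLDM, NGTDM. All operate on a quantized
## integer array `q` (levels 1..ng inside the region, 0 outside) as produced
## by discretize(). Matrix-level functions are exported so brute-force
## enumeration oracles can check the construction directly.

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts symmetric co-occurrences of gray levels at voxel pairs separated
#' by `direction` (times `distance`), both voxels inside the region.
#'
#' @param q integer array of levels (0 outside the region).
#' @param ng number of gray levels.
#' @param direction integer offset (length 3).
#' @param distance voxel distance (default 1).
#' @return ng x ng symmetric count matrix.
#' @export
glcm_matrix <- function(q, ng, direction, distance = 1) {
  off <- as.integer(direction) * as.integer(distance)
  qb <- shift_array(q, -off, fill = 0L)  # qb(x) = q(x + off)
  ok <- q > 0L & qb > 0L
  if (!any(ok)) return(matrix(0, ng, ng))
  counts <- tabulate((q[ok] - 1L) * ng + qb[ok], ng * ng)
  m <- matrix(counts, ng, ng, byrow = TRUE)
  m + t(m)
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal gray level along `direction`; rows are gray
#' levels, columns run lengths.
#'
#' @inheritParams glcm_matrix
#' @return ng x Lmax count matrix.
#' @export
glrlm_matrix <- function(q, ng, direction) {
  d <- dim(q)
  idx <- which(q > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, ng, 1))
  dirv <- as.integer(direction)
  ## parametrize position along the line by the first nonzero component
  ax <- which(dirv != 0)[1]
  t_par <- idx[, ax] * sign(dirv[ax])  # |dirv[ax]| == 1 for unit offsets
  line_id <- idx - t_par %*% t(dirv)
  ## numeric line key: coordinates of line_id are bounded by +/- max(dim)
  base <- 2 * max(d) + 3
  key <- (line_id[, 1] + max(d)) +
    (line_id[, 2] + max(d)) * base +
    (line_id[, 3] + max(d)) * base^2
  ord <- order(key, t_par)
  g <- q[idx][ord]
  keyo <- key[ord]; to <- t_par[ord]
  newrun <- c(TRUE, keyo[-1] != keyo[-length(keyo)] |
                diff(to) != 1L | g[-1] != g[-length(g)])
  run_id <- cumsum(newrun)
  lens <- tabulate(run_id)
  gray <- g[newrun]
  lmax <- max(lens)
  m <- matrix(0, ng, lmax)
  tab <- tabulate((gray - 1L) * lmax + lens, ng * lmax)
  matrix(tab, ng, lmax, byrow = TRUE)
}

#' Gray-level size zone matrix
#'
#' Counts 26-connected zones of equal gray level by size; rows are gray
#' levels, columns zone sizes.
#'
#' @inheritParams glcm_matrix
#' @return ng x Smax count matrix.
#' @export
glszm_matrix <- function(q, ng) {
  zones <- connected_zones(q)
  if (length(zones$size) == 0L) return(matrix(0, ng, 1))
  smax <- max(zones$size)
  tab <- tabulate((zones$gray - 1L) * smax + zones$size, ng * smax)
  matrix(tab, ng, smax, byrow = TRUE)
}

## 26-connected equal-gray zones via minimum-label propagation on the
## in-region voxel list (adjacency precomputed once, then vectorized pmin
## sweeps until convergence).
connected_zones <- function(q) {
  d <- dim(q)
  vox <- which(q > 0L)
  n_in <- length(vox)
  if (n_in == 0L) return(list(gray = integer(0), size = integer(0)))
  id_arr <- array(0L, d)
  id_arr[vox] <- seq_len(n_in)
  coords <- arrayInd(vox, d)
  g <- q[vox]
  offs <- neighbor_offsets_26()
  nb <- matrix(0L, n_in, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nc1 <- coords[, 1] + offs[i, 1]
    nc2 <- coords[, 2] + offs[i, 2]
    nc3 <- coords[, 3] + offs[i, 3]
    ok <- nc1 >= 1L & nc1 <= d[1] & nc2 >= 1L & nc2 <= d[2] &
      nc3 >= 1L & nc3 <= d[3]
    lin <- nc1 + (nc2 - 1L) * d[1] + (nc3 - 1L) * d[1] * d[2]
    cand <- integer(n_in)
    cand[ok] <- id_arr[lin[ok]]
    same <- cand > 0L
    same[same] <- g[cand[same]] == g[which(same)]
    cand[!same] <- 0L
    nb[, i] <- cand
  }
  lab <- seq_len(n_in)
  repeat {
    new_lab <- lab
    for (i in seq_len(ncol(nb))) {
      has <- nb[, i] > 0L
      new_lab[has] <- pmin(new_lab[has], lab[nb[has, i]])
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
    lab <- lab[lab]  # pointer-jump to speed convergence on long zones
  }
  first <- !duplicated(lab)
  sizes <- tabulate(match(lab, lab[first]))
  list(gray = g[first], size = sizes)
}

#' Gray-level dependence matrix
#'
#' For each region voxel, the dependence is the number of 26-neighbors
#' inside the region whose gray level differs by at most `alpha`; rows are
#' gray levels, columns dependence + 1 (0..26 neighbors).
#'
#' @inheritParams glcm_matrix
#' @param alpha gray-level tolerance (default 0).
#' @return ng x 27 count matrix.
#' @export
gldm_matrix <- function(q, ng, alpha = 0) {
  inside <- q > 0L
  dep <- array(0L, dim(q))
  offs <- neighbor_offsets_26()
  for (i in seq_len(nrow(offs))) {
    nb <- shift_array(q, offs[i, ], fill = 0L)
    dep <- dep + (inside & nb > 0L & abs(nb - q) <= alpha)
  }
  dmax <- 26L
  tab <- tabulate((q[inside] - 1L) * (dmax + 1L) + dep[inside] + 1L,
                  ng * (dmax + 1L))
  matrix(tab, ng, dmax + 1L, byrow = TRUE)
}

#' Neighboring gray-tone difference matrix ingredients
#'
#' For each gray level g: `n_g` (count of region voxels of level g having at
#' least one region neighbor), and `s_g` (sum over those voxels of the
#' absolute difference between g and the mean level of their 26-neighbors
#' inside the region).
#'
#' @inheritParams glcm_matrix
#' @return list with vectors `n` and `s` (length ng) and `n_valid`.
#' @export
ngtdm_stats <- function(q, ng) {
  inside <- q > 0L
  ssum <- array(0, dim(q)); cnt <- array(0L, dim(q))
  offs <- neighbor_offsets_26()
  for (i in seq_len(nrow(offs))) {
    nb <- shift_array(q, offs[i, ], fill = 0L)
    ok <- nb > 0L
    ssum <- ssum + ifelse(ok, nb, 0)
    cnt <- cnt + ok
  }
  valid <- inside & cnt > 0L
  adiff <- abs(q[valid] - ssum[valid] / cnt[valid])
  g <- q[valid]
  n_g <- tabulate(g, ng)
  s_g <- vapply(seq_len(ng), function(l) sum(adiff[g == l]), numeric(1))
  list(n = n_g, s = s_g, n_valid = sum(valid))
}

glcm_feature_names <- function() {
  c("Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MaximumProbability", "SumEntropy")
}

## Features of one (already symmetric) GLCM count matrix.
glcm_features_one <- function(m) {
  tot <- sum(m)
  nm <- glcm_feature_names()
  if (tot == 0) return(setNames(rep(NA_real_, length(nm)), nm))
  ng <- nrow(m)
  p <- m / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  kd <- 0:(ng - 1)
  pxmy <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  pxpy <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))
  ent0 <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  da <- sum(kd * pxmy)
  hxy <- ent0(p)
  pp <- outer(px, py)
  hxy1 <- -sum(p[pp > 0] * log2(pp[pp > 0]))
  hxy2 <- ent0(pp)
  hx <- ent0(px); hy <- ent0(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigx > 1e-12 && sigy > 1e-12) {
    (sum(i * j * p) - mux * muy) / (sigx * sigy)
  } else NA_real_
  off <- abs(i - j) > 0
  setNames(c(
    sum(i * j * p),
    sum((i + j - mux - muy)^4 * p),
    sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    ent0(pxmy),
    sum((kd - da)^2 * pxmy),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p / (1 + abs(i - j) / ng)),
    imc1,
    imc2,
    sum(p[off] / (i - j)[off]^2),
    mux,
    sum(p^2),
    hxy,
    max(p),
    ent0(pxpy)
  ), nm)
}

#' GLCM features (21), averaged over the 13 unique 3D directions
#'
#' @param q integer array of levels (0 outside the region).
#' @param ng number of gray levels.
#' @param distance voxel distance (default 1).
#' @return named numeric vector of length 21.
#' @export
glcm_features <- function(q, ng, distance = 1) {
  dirs <- unique_directions_13()
  per <- vapply(seq_len(nrow(dirs)), function(r) {
    glcm_features_one(glcm_matrix(q, ng, dirs[r, ], distance))
  }, numeric(21))
  rowMeans(per, na.rm = TRUE)
}

glrlm_feature_names <- function() {
  c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis")
}

glrlm_features_one <- function(m, np) {
  nm <- glrlm_feature_names()
  nr <- sum(m)
  if (nr == 0) return(setNames(rep(NA_real_, length(nm)), nm))
  ng <- nrow(m); lmax <- ncol(m)
  g <- matrix(seq_len(ng), ng, lmax)
  l <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  p <- m / nr
  rg <- rowSums(m); rl <- colSums(m)
  mug <- sum(g * p); mul <- sum(l * p)
  pv <- p[p > 0]
  setNames(c(
    sum(rg^2) / nr,
    sum(rg^2) / nr^2,
    sum((g - mug)^2 * p),
    sum(m * g^2) / nr,
    sum(m * l^2) / nr,
    sum(m * g^2 * l^2) / nr,
    sum(m * l^2 / g^2) / nr,
    sum(m / g^2) / nr,
    -sum(pv * log2(pv)),
    sum(rl^2) / nr,
    sum(rl^2) / nr^2,
    nr / np,
    sum((l - mul)^2 * p),
    sum(m / l^2) / nr,
    sum(m * g^2 / l^2) / nr,
    sum(m / (g^2 * l^2)) / nr
  ), nm)
}

#' GLRLM features (16), averaged over the 13 unique 3D directions
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(q, ng) {
  np <- sum(q > 0L)
  dirs <- unique_directions_13()
  per <- vapply(seq_len(nrow(dirs)), function(r) {
    glrlm_features_one(glrlm_matrix(q, ng, dirs[r, ]), np)
  }, numeric(16))
  rowMeans(per, na.rm = TRUE)
}

glszm_feature_names <- function() {
  c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance")
}

#' GLSZM features (16)
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(q, ng) {
  m <- glszm_matrix(q, ng)
  np <- sum(q > 0L)
  nm <- glszm_feature_names()
  nz <- sum(m)
  if (nz == 0) return(setNames(rep(NA_real_, length(nm)), nm))
  smax <- ncol(m)
  g <- matrix(seq_len(ng), ng, smax)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  p <- m / nz
  zg <- rowSums(m); zs <- colSums(m)
  mug <- sum(g * p); mus <- sum(s * p)
  pv <- p[p > 0]
  setNames(c(
    sum(zg^2) / nz,
    sum(zg^2) / nz^2,
    sum((g - mug)^2 * p),
    sum(m * g^2) / nz,
    sum(m * s^2) / nz,
    sum(m * g^2 * s^2) / nz,
    sum(m * s^2 / g^2) / nz,
    sum(m / g^2) / nz,
    sum(zs^2) / nz,
    sum(zs^2) / nz^2,
    sum(m / s^2) / nz,
    sum(m * g^2 / s^2) / nz,
    sum(m / (g^2 * s^2)) / nz,
    -sum(pv * log2(pv)),
    nz / np,
    sum((s - mus)^2 * p)
  ), nm)
}

gldm_feature_names <- function() {
  c("DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis")
}

#' GLDM features (14)
#' @inheritParams glcm_features
#' @param alpha gray-level dependence tolerance.
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(q, ng, alpha = 0) {
  m <- gldm_matrix(q, ng, alpha)
  nm <- gldm_feature_names()
  nz <- sum(m)
  if (nz == 0) return(setNames(rep(NA_real_, length(nm)), nm))
  dmax <- ncol(m)
  g <- matrix(seq_len(ng), ng, dmax)
  j <- matrix(seq_len(dmax), ng, dmax, byrow = TRUE)  # dependence + 1
  p <- m / nz
  dg <- rowSums(m); dd <- colSums(m)
  mug <- sum(g * p); mud <- sum(j * p)
  pv <- p[p > 0]
  setNames(c(
    -sum(pv * log2(pv)),
    sum(dd^2) / nz,
    sum(dd^2) / nz^2,
    sum((j - mud)^2 * p),
    sum(dg^2) / nz,
    sum((g - mug)^2 * p),
    sum(m * g^2) / nz,
    sum(m * j^2) / nz,
    sum(m * g^2 * j^2) / nz,
    sum(m * j^2 / g^2) / nz,
    sum(m / g^2) / nz,
    sum(m / j^2) / nz,
    sum(m * g^2 / j^2) / nz,
    sum(m / (g^2 * j^2)) / nz
  ), nm)
}

ngtdm_feature_names <- function() {
  c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
}

#' NGTDM features (5)
#' @inheritParams glcm_features
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(q, ng) {
  st <- ngtdm_stats(q, ng)
  nm <- ngtdm_feature_names()
  nv <- st$n_valid
  if (nv == 0) return(setNames(rep(NA_real_, 5L), nm))
  pg <- st$n / nv
  sg <- st$s
  gl <- seq_len(ng)
  nz <- pg > 0
  ngp <- sum(nz)
  coarse_den <- sum(pg * sg)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pg[nz], pg[nz]) * outer(gl[nz], gl[nz], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(sg) / nv)
  } else 0
  busy_den <- sum(abs(outer(gl[nz] * pg[nz], gl[nz] * pg[nz], `-`)))
  busyness <- if (busy_den > 0) sum(pg * sg) / busy_den else 0
  complexity <- if (ngp > 0) {
    num <- outer(gl[nz], gl[nz], function(a, b) abs(a - b)) *
      (outer(pg[nz] * sg[nz], rep(1, ngp)) +
         outer(rep(1, ngp), pg[nz] * sg[nz])) /
      (outer(pg[nz], rep(1, ngp)) + outer(rep(1, ngp), pg[nz]))
    sum(num) / nv
  } else 0
  strength <- if (sum(sg) > 0) {
    sum((outer(pg[nz], rep(1, ngp)) + outer(rep(1, ngp), pg[nz])) *
          outer(gl[nz], gl[nz], `-`)^2) / sum(sg)
  } else 0
  setNames(c(busyness, coarseness, complexity, contrast, strength), nm)
}
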