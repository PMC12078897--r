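#' Multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity as a low-order
#' polynomial in the log domain, fitted robustly (bisquare M-estimation) so
#' genuine anatomy is treated as outliers to the slowly varying field, and
#' divides it out. The estimated field is rescaled to unit geometric mean
#' inside the mask, so the within-mask mean intensity is preserved.
#'
#' @param volume a [volume3d()], strictly positive inside `mask`.
#' @param mask optional `mask3d` defining the fit region; default the whole
#'   grid.
#' @param order polynomial degree of the field (default cubic).
#' @return A list with `corrected` (volume3d), `bias` (volume3d, estimated
#'   multiplicative field).
#' @export
correct_bias <- function(volume, mask = NULL, order = 3) {
  d <- dim(volume$data)
  if (is.null(mask)) mask <- mask3d(array(1L, d), volume$spacing)
  check_same_grid(volume, mask)
  inside <- mask$data != 0L
  if (!any(inside)) abort("mask is empty.")
  if (any(volume$data[inside] <= 0)) {
    abort("bias correction requires strictly positive intensities inside the mask.")
  }
  g <- coord_grids(d)
  xn <- (as.vector(g$x) - (d[1] + 1) / 2) / d[1]
  yn <- (as.vector(g$y) - (d[2] + 1) / 2) / d[2]
  zn <- (as.vector(g$z) - (d[3] + 1) / 2) / d[3]
  basis <- polynomial_basis_3d(xn, yn, zn, order)
  sel <- as.vector(inside) & as.vector(volume$data) > 0
  logv <- log(as.vector(volume$data)[sel])
  if (sd(logv) < 1e-12) {
    ## constant volume: nothing to correct
    return(list(corrected = volume,
                bias = volume3d(array(1, d), volume$spacing)))
  }
  fit <- MASS::rlm(basis[sel, , drop = FALSE], logv, maxit = 100,
                   psi = MASS::psi.bisquare)
  logfield <- as.vector(basis %*% coef(fit))
  ## remove the constant part: unit geometric mean inside the mask
  logfield <- logfield - mean(logfield[as.vector(inside)])
  bias <- array(exp(logfield), d)
  out <- volume
  out$data <- volume$data / bias
  list(corrected = out, bias = volume3d(bias, volume$spacing))
}

polynomial_basis_3d <- function(x, y, z, order) {
  terms <- list(rep(1, length(x)))
  for (total in 1:order) {
    for (i in 0:total) for (j in 0:(total - i)) {
      k <- total - i - j
      terms[[length(terms) + 1L]] <- x^i * y^j * z^k
    }
  }
  do.call(cbind, terms)
}

#' Resample a volume to isotropic spacing
#'
#' @param volume a [volume3d()] or [mask3d()].
#' @param spacing target isotropic spacing in mm (default 1).
#' @param mode `"linear"` (trilinear, for intensity volumes) or `"nearest"`
#'   (for label masks). Masks passed without an explicit mode are resampled
#'   nearest-neighbor automatically.
#' @return the resampled volume on the new grid; physical extent preserved
#'   within one voxel.
#' @export
resample_isotropic <- function(volume, spacing = 1,
                               mode = c("auto", "linear", "nearest")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (inherits(volume, "mask3d")) "nearest" else "linear"
  }
  d <- dim(volume$data)
  if (any(d == 0L)) abort("degenerate volume.")
  old_sp <- volume$spacing
  if (max(abs(old_sp - spacing)) < 1e-9) return(volume)
  new_d <- pmax(1L, as.integer(round(d * old_sp / spacing)))
  g <- coord_grids(new_d)
  ## voxel centers: world = (i - 1) * spacing + origin
  xs <- (as.vector(g$x) - 1) * spacing / old_sp[1] + 1
  ys <- (as.vector(g$y) - 1) * spacing / old_sp[2] + 1
  zs <- (as.vector(g$z) - 1) * spacing / old_sp[3] + 1
  vals <- if (mode == "nearest") {
    interp_nearest(volume$data, xs, ys, zs)
  } else {
    interp_trilinear(volume$data, xs, ys, zs)
  }
  arr <- array(vals, new_d)
  if (inherits(volume, "mask3d")) {
    mask3d(arr, rep(spacing, 3), volume$origin, volume$sequence)
  } else {
    volume3d(arr, rep(spacing, 3), volume$origin, volume$sequence)
  }
}

#' Learn decile landmarks for histogram standardization
#'
#' Two-stage landmark method: each training volume's within-mask intensity
#' deciles are affinely mapped to a fixed standard scale (pinning the 1st and
#' 99th percentiles to the scale ends), and the mapped deciles are averaged
#' across volumes to give the model landmarks. [standardize_histogram()] then
#' maps a volume's deciles piecewise-linearly onto them. The transform is
#' monotone and idempotent.
#'
#' @param volumes list of [volume3d()] training volumes (>= 2, or one volume
#'   repeated).
#' @param masks optional list of `mask3d` fit regions (default whole grid).
#' @param standard_scale intensity pair (min, max) of the standard scale.
#' @return A `landmark_model` with fields `standard_scale`, `mean_landmarks`
#'   (positions of percentiles 1, 10, ..., 90, 99 on the standard scale).
#' @export
learn_landmarks <- function(volumes, masks = NULL,
                            standard_scale = c(0, 100)) {
  if (length(volumes) < 2L) abort("need at least 2 training volumes.")
  probs <- c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)
  mapped <- vapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    vals <- if (is.null(masks)) as.vector(v$data) else
      mask_values(v, masks[[i]])
    q <- quantile(vals, probs, names = FALSE, type = 1)
    if (q[length(q)] - q[1] < 1e-12) {
      abort("constant volume: cannot place landmarks.")
    }
    ## affine map pinning p1 -> scale min, p99 -> scale max
    standard_scale[1] + (q - q[1]) / (q[length(q)] - q[1]) *
      diff(standard_scale)
  }, numeric(length(probs)))
  lm_mean <- rowMeans(mapped)
  if (any(diff(lm_mean) <= 0)) {
    ## enforce strict monotonicity (ties can arise from discrete data)
    lm_mean <- cummax(lm_mean + seq_along(lm_mean) * 1e-9)
  }
  structure(list(standard_scale = standard_scale, probs = probs,
                 mean_landmarks = lm_mean),
            class = "landmark_model")
}

#' @rdname learn_landmarks
#' @param volume volume to standardize.
#' @param model a `landmark_model`.
#' @param mask optional `mask3d` on which the volume's landmarks are
#'   computed.
#' @return `standardize_histogram()`: the volume mapped onto the standard
#'   scale.
#' @export
standardize_histogram <- function(volume, model, mask = NULL) {
  vals <- if (is.null(mask)) as.vector(volume$data) else
    mask_values(volume, mask)
  q <- quantile(vals, model$probs, names = FALSE, type = 1)
  if (q[length(q)] - q[1] < 1e-12) {
    abort("constant volume: cannot standardize.")
  }
  q <- cummax(q + seq_along(q) * 1e-12)
  out <- volume
  out$data[] <- approx(q, model$mean_landmarks, xout = as.vector(volume$data),
                       rule = 2)$y
  out
}

## Mutual information between two equal-length intensity vectors (histogram
## estimator, `bins` x `bins`).
mutual_information <- function(a, b, bins = 32) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) < 1e-12 || diff(rb) < 1e-12) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1L, 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(a)
  pa <- tabulate(ia, bins) / length(a)
  pb <- tabulate(ib, bins) / length(b)
  pj <- joint[joint > 0]
  hj <- -sum(pj * log(pj))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  ha + hb - hj
}

#' Register a moving volume to a fixed volume
#'
#' Maximizes mutual information between the fixed volume and the resampled
#' moving volume. The affine stage is initialized by intensity
#' center-of-mass alignment and refined by Nelder-Mead over a rigid
#' translation (default) or a full 12-parameter affine map; an optional
#' deformable stage then runs Gaussian-regularized demons-style refinement.
#'
#' @param moving,fixed [volume3d()] objects on the same grid geometry.
#' @param type `"translation"` or `"affine"`.
#' @param deformable logical; run the deformable refinement stage.
#' @param bins histogram bins for the mutual-information metric.
#' @param deformable_iter,deformable_sigma demons iterations and smoothing
#'   (voxels).
#' @return list with `transform` (class `spatial_transform`: `translation`
#'   mm, `affine` matrix or NULL, `deformation` displacement fields or NULL,
#'   `metric` final MI, `converged`), and `resampled` (moving volume on the
#'   fixed grid).
#' @export
register_volumes <- function(moving, fixed,
                             type = c("translation", "affine"),
                             deformable = FALSE, bins = 32,
                             deformable_iter = 30, deformable_sigma = 1) {
  type <- match.arg(type)
  check_same_grid(moving, fixed)
  d <- dim(fixed$data)
  sp <- fixed$spacing
  g <- coord_grids(d)
  gx <- as.vector(g$x); gy <- as.vector(g$y); gz <- as.vector(g$z)
  fvals <- as.vector(fixed$data)

  resample_translated <- function(t_mm) {
    interp_trilinear(moving$data, gx + t_mm[1] / sp[1],
                     gy + t_mm[2] / sp[2], gz + t_mm[3] / sp[3])
  }
  neg_mi_t <- function(t_mm) -mutual_information(fvals,
                                                resample_translated(t_mm),
                                                bins)

  ## init: intensity center-of-mass difference (above-median mass), then a
  ## coarse-to-fine grid search before the simplex refinement (the MI
  ## surface is smooth but the simplex can stall away from the basin)
  com <- function(v) {
    w <- pmax(as.vector(v$data) - median(as.vector(v$data)), 0)
    c(sum(w * gx), sum(w * gy), sum(w * gz)) / sum(w)
  }
  t0 <- (com(moving) - com(fixed)) * sp
  best <- t0; best_val <- neg_mi_t(t0)
  for (step in c(2.5, 1)) {
    grid <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2) * step
    for (r in seq_len(nrow(grid))) {
      cand <- best + as.numeric(grid[r, ])
      val <- neg_mi_t(cand)
      if (val < best_val) { best_val <- val; best <- cand }
    }
  }
  opt <- optim(best, neg_mi_t, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-8))
  if (opt$value > best_val) { opt$par <- best; opt$value <- best_val }
  converged <- opt$convergence == 0L
  if (!converged) warn("registration optimizer did not fully converge.")
  t_mm <- opt$par
  affine <- NULL

  if (type == "affine") {
    ## 12-parameter map: source = A %*% x + b (voxel coords, then refined)
    cpt <- (d + 1) / 2
    neg_mi_a <- function(par) {
      A <- diag(3) + matrix(par[1:9], 3, 3)
      b <- par[10:12]
      xs <- A[1, 1] * (gx - cpt[1]) + A[1, 2] * (gy - cpt[2]) +
        A[1, 3] * (gz - cpt[3]) + cpt[1] + b[1]
      ys <- A[2, 1] * (gx - cpt[1]) + A[2, 2] * (gy - cpt[2]) +
        A[2, 3] * (gz - cpt[3]) + cpt[2] + b[2]
      zs <- A[3, 1] * (gx - cpt[1]) + A[3, 2] * (gy - cpt[2]) +
        A[3, 3] * (gz - cpt[3]) + cpt[3] + b[3]
      -mutual_information(fvals, interp_trilinear(moving$data, xs, ys, zs),
                          bins)
    }
    par0 <- c(rep(0, 9), t_mm / sp)
    opta <- optim(par0, neg_mi_a, method = "Nelder-Mead",
                  control = list(maxit = 500, reltol = 1e-8))
    affine <- list(A = diag(3) + matrix(opta$par[1:9], 3, 3),
                   b = opta$par[10:12], center = cpt)
    t_mm <- opta$par[10:12] * sp
    res_vals <- {
      A <- affine$A; b <- affine$b
      xs <- A[1, 1] * (gx - cpt[1]) + A[1, 2] * (gy - cpt[2]) +
        A[1, 3] * (gz - cpt[3]) + cpt[1] + b[1]
      ys <- A[2, 1] * (gx - cpt[1]) + A[2, 2] * (gy - cpt[2]) +
        A[2, 3] * (gz - cpt[3]) + cpt[2] + b[2]
      zs <- A[3, 1] * (gx - cpt[1]) + A[3, 2] * (gy - cpt[2]) +
        A[3, 3] * (gz - cpt[3]) + cpt[3] + b[3]
      interp_trilinear(moving$data, xs, ys, zs)
    }
  } else {
    res_vals <- resample_translated(t_mm)
  }

  deformation <- NULL
  if (deformable) {
    ## rank-equalize both volumes so the demons update matches geometry, not
    ## the sequences' different contrast scales
    equalize <- function(a) { a[] <- rank(a) / length(a); a }
    f_eq <- equalize(fixed$data)
    m_arr <- equalize(array(res_vals, d))
    u <- list(array(0, d), array(0, d), array(0, d))
    scl <- sd(as.vector(f_eq))^2
    for (it in seq_len(deformable_iter)) {
      warped <- warp_array(m_arr, u, linear = TRUE)
      diffv <- f_eq - warped
      gr <- array_gradient(warped, c(1, 1, 1))
      gnorm2 <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
      denom <- gnorm2 + diffv^2 / scl
      denom[denom < 1e-8] <- 1e-8
      for (ax in 1:3) {
        step <- diffv * gr[[ax]] / denom
        step[abs(step) > 2] <- sign(step[abs(step) > 2]) * 2
        u[[ax]] <- gaussian_smooth(u[[ax]] + step, deformable_sigma)
      }
    }
    deformation <- u
    res_vals <- as.vector(warp_array(array(res_vals, d), u, linear = TRUE))
  }

  resampled <- moving
  resampled$data[] <- res_vals
  transform <- structure(
    list(translation = t_mm, affine = affine, deformation = deformation,
         metric = mutual_information(fvals, res_vals, bins),
         converged = converged),
    class = "spatial_transform"
  )
  list(transform = transform, resampled = resampled)
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf(
    "<spatial_transform> translation (%.2f, %.2f, %.2f) mm%s%s, MI %.4f\n",
    x$translation[1], x$translation[2], x$translation[3],
    if (is.null(x$affine)) "" else " + affine",
    if (is.null(x$deformation)) "" else " + deformable", x$metric
  ))
  invisible(x)
}

## Warp array by displacement fields u (voxel units): out(x) = a(x + u(x)).
warp_array <- function(a, u, linear = TRUE) {
  d <- dim(a)
  g <- coord_grids(d)
  xs <- as.vector(g$x + u[[1]]); ys <- as.vector(g$y + u[[2]])
  zs <- as.vector(g$z + u[[3]])
  out <- a
  out[] <- if (linear) interp_trilinear(a, xs, ys, zs) else
    interp_nearest(a, xs, ys, zs)
  out
}

#' Apply a recovered spatial transform to a volume or mask
#'
#' Resamples `volume` (in the moving frame) onto the fixed grid using the
#' transform returned by [register_volumes()]. Masks are resampled
#' nearest-neighbor.
#'
#' @param volume `volume3d` or `mask3d` in the moving frame.
#' @param transform a `spatial_transform`.
#' @return the transformed volume on the fixed grid.
#' @export
apply_transform <- function(volume, transform) {
  d <- dim(volume$data)
  sp <- volume$spacing
  g <- coord_grids(d)
  nearest <- inherits(volume, "mask3d")
  if (!is.null(transform$affine)) {
    A <- transform$affine$A; b <- transform$affine$b
    cpt <- transform$affine$center
    xs <- A[1, 1] * (g$x - cpt[1]) + A[1, 2] * (g$y - cpt[2]) +
      A[1, 3] * (g$z - cpt[3]) + cpt[1] + b[1]
    ys <- A[2, 1] * (g$x - cpt[1]) + A[2, 2] * (g$y - cpt[2]) +
      A[2, 3] * (g$z - cpt[3]) + cpt[2] + b[2]
    zs <- A[3, 1] * (g$x - cpt[1]) + A[3, 2] * (g$y - cpt[2]) +
      A[3, 3] * (g$z - cpt[3]) + cpt[3] + b[3]
  } else {
    t_mm <- transform$translation
    xs <- g$x + t_mm[1] / sp[1]; ys <- g$y + t_mm[2] / sp[2]
    zs <- g$z + t_mm[3] / sp[3]
  }
  if (!is.null(transform$deformation)) {
    u <- transform$deformation
    xs <- xs + u[[1]]; ys <- ys + u[[2]]; zs <- zs + u[[3]]
  }
  out <- volume
  vals <- if (nearest) {
    interp_nearest(volume$data, as.vector(xs), as.vector(ys), as.vector(zs))
  } else {
    interp_trilinear(volume$data, as.vector(xs), as.vector(ys),
                     as.vector(zs))
  }
  out$data[] <- if (nearest) as.integer(vals) else vals
  out
}

## Central-difference gradient of a 3D array; spacing in mm per axis.
array_gradient <- function(a, spacing) {
  lapply(1:3, function(ax) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    fwd <- shift_array(a, -off)
    bwd <- shift_array(a, off)
    d <- dim(a)
    fwd[is.na(fwd)] <- a[is.na(fwd)]
    bwd[is.na(bwd)] <- a[is.na(bwd)]
    (fwd - bwd) / (2 * spacing[ax])
  })
}

#' Preprocess one patient's volumes
#'
#' Runs the standardization chain in fixed order: bias correction,
#' isotropic resampling, histogram standardization (with a landmark model
#' learned on training volumes only), and DWI-to-T2WI registration (DWI
#' moving, T2WI fixed). The DWI-frame VOI is carried through the recovered
#' transform so all regions live on the common T2WI grid.
#'
#' @param patient a `synthetic_patient` (possibly with artifacts applied).
#' @param landmarks named list with `T2WI` and `DWI` `landmark_model`s, or
#'   NULL to skip standardization.
#' @param spacing target isotropic spacing (mm); NULL to skip resampling.
#' @param register logical; run DWI->T2WI registration.
#' @param deformable logical; include the deformable registration stage.
#' @return the patient with preprocessed `t2w`, `dwi`, resampled masks, and
#'   `registration` (the recovered `spatial_transform`) attached.
#' @export
preprocess_patient <- function(patient, landmarks = NULL, spacing = 1,
                               register = TRUE, deformable = TRUE) {
  patient$t2w <- correct_bias(patient$t2w)$corrected
  patient$dwi <- correct_bias(patient$dwi)$corrected
  if (!is.null(spacing)) {
    patient$t2w <- resample_isotropic(patient$t2w, spacing)
    patient$dwi <- resample_isotropic(patient$dwi, spacing)
    patient$voi <- resample_isotropic(patient$voi, spacing)
    patient$voi_dwi <- resample_isotropic(patient$voi_dwi, spacing)
    patient$true_habitat_map <- lapply(patient$true_habitat_map,
                                       resample_isotropic, spacing = spacing)
  }
  if (!is.null(landmarks)) {
    patient$t2w <- standardize_histogram(patient$t2w, landmarks$T2WI)
    patient$dwi <- standardize_histogram(patient$dwi, landmarks$DWI)
  }
  if (register) {
    reg <- register_volumes(patient$dwi, patient$t2w,
                            deformable = deformable)
    patient$dwi <- reg$resampled
    patient$voi_dwi <- apply_transform(patient$voi_dwi, reg$transform)
    patient$registration <- reg$transform
  }
  patient
}
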