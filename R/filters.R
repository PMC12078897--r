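## Shift with replicate (clamped-edge) padding: out(x) = a(x - off).
shift_clamped <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    pmin(pmax(seq_len(d[ax]) - off[ax], 1L), d[ax])
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## One-level undecimated separable Haar step along an axis.
haar_axis <- function(a, axis, type = c("L", "H")) {
  type <- match.arg(type)
  off <- c(0L, 0L, 0L); off[axis] <- 1L
  nb <- shift_clamped(a, off)
  if (type == "L") (a + nb) / 2 else (a - nb) / 2
}

#' Build the 21-image-type filter bank
#'
#' Produces the filtered variants of a preprocessed volume over which
#' non-shape radiomic features are computed: the original image; the eight
#' sub-bands of a one-level undecimated separable Haar wavelet decomposition
#' (`wavelet_LLL` ... `wavelet_HHH`, letters ordered by axis); scale-
#' normalized Laplacian-of-Gaussian responses at sigma = 1, 2, 3, 4 mm;
#' four monotone intensity transforms (square, square root, logarithm,
#' exponential); the gradient magnitude; and three local-binary-pattern-3D
#' style maps (6-neighbor code, 26-neighbor count, 26-neighborhood excess
#' kurtosis). All outputs live on the input grid.
#'
#' @param volume a preprocessed, isotropically resampled [volume3d()].
#' @param log_sigmas_mm Laplacian-of-Gaussian scales in mm.
#' @param types optional subset of image-type names to compute (default all
#'   21).
#' @return named list of `volume3d` objects (all 21 by default, first
#'   element `original`).
#' @export
build_image_types <- function(volume, log_sigmas_mm = 1:4, types = NULL) {
  a <- volume$data
  sp <- volume$spacing
  d <- dim(a)
  wanted <- function(nm) is.null(types) || nm %in% types
  wrap <- function(arr) volume3d(arr, sp, volume$origin, volume$sequence)
  out <- list()
  if (wanted("original")) out$original <- wrap(a)

  ## wavelet sub-bands
  for (t1 in c("L", "H")) for (t2 in c("L", "H")) for (t3 in c("L", "H")) {
    nm <- paste0("wavelet_", t1, t2, t3)
    if (!wanted(nm)) next
    w <- haar_axis(haar_axis(haar_axis(a, 1, t1), 2, t2), 3, t3)
    out[[nm]] <- wrap(w)
  }

  ## Laplacian of Gaussian, scale-normalized (sigma^2 * laplacian)
  for (s in log_sigmas_mm) {
    if (!wanted(paste0("log_sigma_", s, "_mm"))) next
    if (s > min(d * sp)) {
      abort(sprintf("LoG sigma %g mm exceeds the volume extent.", s))
    }
    sig_vox <- s / sp
    sm <- gaussian_smooth(a, sig_vox)
    lap <- array(0, d)
    for (ax in 1:3) {
      off <- c(0L, 0L, 0L); off[ax] <- 1L
      lap <- lap + (shift_clamped(sm, off) + shift_clamped(sm, -off) -
                      2 * sm) / sp[ax]^2
    }
    out[[paste0("log_sigma_", s, "_mm")]] <- wrap(s^2 * lap)
  }

  ## intensity transforms (monotone, defined for any real input)
  if (wanted("square")) out$square <- wrap(a^2 * sign(a))
  if (wanted("squareroot")) out$squareroot <- wrap(sqrt(abs(a)) * sign(a))
  if (wanted("logarithm")) out$logarithm <- wrap(log(a - min(a) + 1))
  if (wanted("exponential")) {
    mx <- max(abs(a)); if (mx == 0) mx <- 1
    out$exponential <- wrap(exp(a / mx))
  }

  ## gradient magnitude
  if (wanted("gradient")) {
    gr <- array_gradient(a, sp)
    out$gradient <- wrap(sqrt(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2))
  }

  ## LBP-3D style maps
  if (wanted("lbp_3d_m1")) {
    face_offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
    m1 <- array(0, d)
    for (i in seq_len(nrow(face_offs))) {
      m1 <- m1 + 2^(i - 1) * (shift_clamped(a, face_offs[i, ]) >= a)
    }
    out$lbp_3d_m1 <- wrap(m1)
  }
  if (wanted("lbp_3d_m2") || wanted("lbp_3d_k")) {
    offs26 <- neighbor_offsets_26()
    cnt <- array(0, d)
    s1 <- array(0, d); s2 <- array(0, d); s3 <- array(0, d); s4 <- array(0, d)
    for (i in seq_len(nrow(offs26))) {
      nb <- shift_clamped(a, offs26[i, ])
      cnt <- cnt + (nb >= a)
      s1 <- s1 + nb; s2 <- s2 + nb^2; s3 <- s3 + nb^3; s4 <- s4 + nb^4
    }
    n <- nrow(offs26)
    mu <- s1 / n
    vv <- pmax(s2 / n - mu^2, 0)
    m4 <- s4 / n - 4 * mu * s3 / n + 6 * mu^2 * s2 / n - 3 * mu^4
    kurt <- ifelse(vv > 1e-12, m4 / vv^2 - 3, 0)
    if (wanted("lbp_3d_m2")) out$lbp_3d_m2 <- wrap(cnt)
    if (wanted("lbp_3d_k")) out$lbp_3d_k <- wrap(kurt)
  }

  if (is.null(types)) stopifnot(length(out) == 21L)
  out
}
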