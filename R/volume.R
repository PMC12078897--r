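#' 3D image volumes and label masks
#'
#' `volume3d()` wraps a numeric 3D array together with its voxel spacing (mm),
#' world origin and an MRI sequence tag (`"T2WI"` or `"DWI"`). `mask3d()` is
#' the integer-labelled counterpart used for tumor volumes of interest (VOI)
#' and habitat maps: 0 marks background, positive integers label regions.
#' Both are plain S3 objects so voxel data stay directly addressable as
#' arrays.
#'
#' @param data numeric (or integer for masks) 3D array of voxel values.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param origin numeric length-3 world-space position of voxel (1,1,1), mm.
#' @param sequence optional sequence tag, e.g. `"T2WI"` or `"DWI"`.
#' @return An object of class `volume3d` (or `mask3d`, which inherits from
#'   `volume3d`).
#' @examples
#' v <- volume3d(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1, 2))
#' voxel_volume(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     sequence = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (any(dim(data) == 0L)) abort("`data` has a zero-extent dimension.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         sequence = sequence),
    class = "volume3d"
  )
}

#' @rdname volume3d
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   sequence = NULL) {
  storage.mode(data) <- "integer"
  v <- volume3d(data, spacing, origin, sequence)
  class(v) <- c("mask3d", class(v))
  v
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
    class(x)[1], d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    if (is.null(x$sequence)) "" else paste0(", sequence ", x$sequence)
  ))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param volume a `volume3d` or `mask3d`.
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

#' Within-mask voxel values
#' @param volume a `volume3d`.
#' @param mask a `mask3d` on the same grid; nonzero voxels define the region.
#' @return numeric vector of voxel values inside the mask.
#' @export
mask_values <- function(volume, mask) {
  check_same_grid(volume, mask)
  volume$data[mask$data != 0L]
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    abort("volume and mask grids differ in shape.")
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    abort("volume and mask voxel spacings differ.")
  }
  invisible(TRUE)
}

#' Voxel-index coordinates of nonzero mask voxels
#'
#' @param mask a `mask3d`.
#' @param label optional label to select; default any nonzero voxel.
#' @return integer matrix with one row per voxel and columns i, j, k.
#' @export
mask_indices <- function(mask, label = NULL) {
  sel <- if (is.null(label)) mask$data != 0L else mask$data == label
  which(sel, arr.ind = TRUE)
}

#' Center of mass of a mask in world mm
#' @param mask a `mask3d`.
#' @return numeric length-3 center of mass (mm).
#' @export
mask_center_of_mass <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) == 0L) abort("mask is empty.")
  unname((colMeans(idx) - 1) * mask$spacing + mask$origin)
}

#' Dice overlap of two binary masks
#' @param a,b `mask3d` objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  check_same_grid(a, b)
  ai <- a$data != 0L
  bi <- b$data != 0L
  denom <- sum(ai) + sum(bi)
  if (denom == 0) return(NA_real_)
  2 * sum(ai & bi) / denom
}

## Shift an array by an integer voxel offset, padding with `fill`.
## Used throughout the texture engine and filters.
shift_array <- function(a, offset, fill = NA) {
  d <- dim(a)
  src <- lapply(1:3, function(ax) {
    idx <- seq_len(d[ax]) - offset[ax]
    idx[idx < 1L | idx > d[ax]] <- NA_integer_
    idx
  })
  out <- array(fill, d)
  ok1 <- !is.na(src[[1]]); ok2 <- !is.na(src[[2]]); ok3 <- !is.na(src[[3]])
  out[ok1, ok2, ok3] <- a[src[[1]][ok1], src[[2]][ok2], src[[3]][ok3]]
  out
}

## The 13 unique 3D direction offsets (one per +/- pair).
unique_directions_13 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- apply(dirs, 1, function(d) {
    d[d != 0][1] > 0  # keep one representative of each +/- pair
  })
  as.matrix(dirs[keep, , drop = FALSE])
}

## All 26 neighbor offsets.
neighbor_offsets_26 <- function() {
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
}
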