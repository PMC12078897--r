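#' Read and write volumes, masks and tables
#'
#' Volumes and masks are stored as NIfTI (optionally gzipped); voxel data
#' round-trip exactly (float64 for volumes, integer for masks) and spacing
#' survives to within 1e-6 mm. Tables are plain CSV.
#'
#' @param path file path (`.nii` or `.nii.gz` for volumes).
#' @param sequence optional sequence tag attached on read.
#' @return `read_volume()` a [volume3d()]; `read_mask()` a [mask3d()];
#'   `read_table()` a tibble.
#' @export
read_volume <- function(path, sequence = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  volume3d(arr, sp[seq_len(3)], sequence = sequence)
}

#' @rdname read_volume
#' @param volume a [volume3d()] (or [mask3d()] for `write_mask()`).
#' @export
write_volume <- function(volume, path) {
  arr <- volume$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  arr <- v$data
  if (max(abs(arr - round(arr))) > 1e-6) {
    abort(sprintf("mask file %s holds non-integer labels.", path))
  }
  mask3d(array(as.integer(round(arr)), dim(arr)), v$spacing, v$origin)
}

#' @rdname read_volume
#' @param mask a [mask3d()].
#' @export
write_mask <- function(mask, path) {
  arr <- mask$data
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_table <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_volume
#' @param table data frame to write.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Check that a volume and mask share a grid, naming both files
#' @param volume_path,mask_path file paths.
#' @return invisibly a list with the loaded volume and mask; errors on any
#'   grid mismatch.
#' @export
read_volume_mask_pair <- function(volume_path, mask_path) {
  v <- read_volume(volume_path)
  m <- read_mask(mask_path)
  ok <- tryCatch({ check_same_grid(v, m); TRUE }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf("grid mismatch between volume %s and mask %s.",
                  volume_path, mask_path))
  }
  invisible(list(volume = v, mask = m))
}
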