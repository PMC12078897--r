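#' Radiomic feature extraction configuration
#'
#' Controls the image-type filter bank, the discretization bin width, and
#' the GLCM distance. With the full 21-type bank each region yields
#' 14 shape + 90 x 21 = 1904 features, with per-class counts
#' 378 (first-order), 14 (shape), 441 (GLCM), 336 (GLRLM), 336 (GLSZM),
#' 294 (GLDM) and 105 (NGTDM).
#'
#' Discretization uses a fixed bin width on the original image; derived
#' image types use the same width rescaled by the ratio of their robust
#' (1st-99th percentile) intensity range to the original's, so filter
#' outputs on much smaller numeric scales still quantize into a comparable
#' number of levels.
#'
#' @param image_types character vector of image-type names to compute, or
#'   `"all"` for the full 21-type bank.
#' @param bin_width fixed bin width on the original intensity scale.
#' @param glcm_distance co-occurrence distance in voxels.
#' @param log_sigmas_mm Laplacian-of-Gaussian scales (mm).
#' @return a `feature_config` list.
#' @export
feature_config <- function(image_types = "all", bin_width = 25,
                           glcm_distance = 1, log_sigmas_mm = 1:4) {
  all_types <- c("original",
                 paste0("wavelet_", c("LLL", "LLH", "LHL", "LHH",
                                      "HLL", "HLH", "HHL", "HHH")),
                 paste0("log_sigma_", log_sigmas_mm, "_mm"),
                 "square", "squareroot", "logarithm", "exponential",
                 "gradient", "lbp_3d_m1", "lbp_3d_m2", "lbp_3d_k")
  if (identical(image_types, "all")) image_types <- all_types
  if (!all(image_types %in% all_types)) {
    abort("unknown image type requested.")
  }
  structure(list(image_types = image_types, bin_width = bin_width,
                 glcm_distance = glcm_distance,
                 log_sigmas_mm = log_sigmas_mm),
            class = "feature_config")
}

#' Expected per-class feature counts for a configuration
#'
#' @param config a [feature_config()].
#' @return named integer vector (firstorder, shape, glcm, glrlm, glszm,
#'   gldm, ngtdm, total).
#' @export
feature_class_counts <- function(config = feature_config()) {
  k <- length(config$image_types)
  counts <- c(firstorder = 18L * k, shape = 14L, glcm = 21L * k,
              glrlm = 16L * k, glszm = 16L * k, gldm = 14L * k,
              ngtdm = 5L * k)
  c(counts, total = sum(counts))
}

#' Extract all radiomic features for one region
#'
#' Computes shape features on the mask plus, for every configured image
#' type, first-order and the five texture-matrix families on the
#' discretized region.
#'
#' @param volume preprocessed [volume3d()] (original image).
#' @param mask `mask3d` region (nonzero voxels).
#' @param config a [feature_config()].
#' @param image_types optional precomputed [build_image_types()] output for
#'   `volume` (reused across regions of the same volume).
#' @return named numeric vector; names are `image_type|class|feature`
#'   (shape features carry image type `original`).
#' @export
extract_region_features <- function(volume, mask, config = feature_config(),
                                    image_types = NULL) {
  check_same_grid(volume, mask)
  if (sum(mask$data != 0L) == 0L) abort("region mask is empty.")
  if (is.null(image_types)) {
    image_types <- build_image_types(volume, config$log_sigmas_mm,
                                     types = config$image_types)
  }
  ## crop to the mask bounding box (margin 1): exact for every feature
  ## family (neighbors outside the region never contribute) and much faster
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  d <- dim(mask$data)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask_c <- mask3d(crop(mask$data), mask$spacing)
  base_rng <- robust_range(mask_values(volume, mask))
  out <- list()
  sf <- shape_features(mask_c)
  names(sf) <- paste0("original|shape|", names(sf))
  out[["shape"]] <- sf
  mask <- mask_c
  for (ty in config$image_types) {
    v <- image_types[[ty]]
    v <- volume3d(crop(v$data), v$spacing, v$origin, v$sequence)
    vals_rng <- robust_range(mask_values(v, mask))
    bw <- config$bin_width
    if (ty != "original" && base_rng > 0) {
      rel <- vals_rng / base_rng
      bw <- max(bw * rel, .Machine$double.eps)
    }
    if (vals_rng == 0) bw <- max(bw, .Machine$double.eps)
    fo <- first_order_features(v, mask, bin_width = bw)
    names(fo) <- paste0(ty, "|firstorder|", names(fo))
    q <- discretize(v, mask, bw)
    ng <- q$n_levels
    tex <- c(
      setNames(glcm_features(q$levels, ng, config$glcm_distance),
               paste0(ty, "|glcm|", glcm_feature_names())),
      setNames(glrlm_features(q$levels, ng),
               paste0(ty, "|glrlm|", glrlm_feature_names())),
      setNames(glszm_features(q$levels, ng),
               paste0(ty, "|glszm|", glszm_feature_names())),
      setNames(gldm_features(q$levels, ng),
               paste0(ty, "|gldm|", gldm_feature_names())),
      setNames(ngtdm_features(q$levels, ng),
               paste0(ty, "|ngtdm|", ngtdm_feature_names()))
    )
    out[[ty]] <- c(fo, tex)
  }
  unlist(out, use.names = TRUE) -> v
  names(v) <- sub("^[^|]*\\.", "", names(v))  # drop the list-name prefix
  v
}

#' Canonical feature names for a configuration (region prefix excluded)
#' @param config a [feature_config()].
#' @return character vector of `image_type|class|feature` names.
#' @export
feature_names <- function(config = feature_config()) {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
          "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
          "Uniformity")
  sh <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
          "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
          "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
          "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
          "Elongation", "Flatness")
  out <- paste0("original|shape|", sh)
  for (ty in config$image_types) {
    out <- c(out,
             paste0(ty, "|firstorder|", fo),
             paste0(ty, "|glcm|", glcm_feature_names()),
             paste0(ty, "|glrlm|", glrlm_feature_names()),
             paste0(ty, "|glszm|", glszm_feature_names()),
             paste0(ty, "|gldm|", gldm_feature_names()),
             paste0(ty, "|ngtdm|", ngtdm_feature_names()))
  }
  out
}

robust_range <- function(x) {
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  diff(q)
}

#' Extract the six-region feature set of one patient
#'
#' Regions follow the habitat-imaging design: whole tumor on each sequence
#' plus the two habitat subregions per sequence. Filter banks are computed
#' once per sequence and shared across its regions. An empty habitat region
#' yields a missing (all-NA) block with a warning.
#'
#' @param t2w,dwi preprocessed [volume3d()] volumes on a common grid.
#' @param region_masks named list of `mask3d` with entries `whole_T2WI`,
#'   `whole_DWI`, `T2WI_habitat1`, `T2WI_habitat2`, `DWI_habitat1`,
#'   `DWI_habitat2`.
#' @param config a [feature_config()].
#' @return one-row tibble; columns named `region|image_type|class|feature`.
#' @export
extract_feature_vector <- function(t2w, dwi, region_masks,
                                   config = feature_config()) {
  needed <- c("whole_T2WI", "whole_DWI", "T2WI_habitat1", "T2WI_habitat2",
              "DWI_habitat1", "DWI_habitat2")
  if (!all(needed %in% names(region_masks))) {
    abort(paste("region_masks must contain:", paste(needed, collapse = ", ")))
  }
  banks <- list(
    T2WI = build_image_types(t2w, config$log_sigmas_mm,
                             types = config$image_types),
    DWI = build_image_types(dwi, config$log_sigmas_mm,
                            types = config$image_types)
  )
  cols <- list()
  for (rg in needed) {
    sq <- if (grepl("T2WI", rg)) "T2WI" else "DWI"
    vol <- if (sq == "T2WI") t2w else dwi
    msk <- region_masks[[rg]]
    if (sum(msk$data != 0L) == 0L) {
      warn(sprintf("region %s is empty; features emitted as missing.", rg))
      nm <- feature_names(config)
      fv <- setNames(rep(NA_real_, length(nm)), nm)
    } else {
      fv <- extract_region_features(vol, msk, config, banks[[sq]])
    }
    names(fv) <- paste0(rg, "|", names(fv))
    cols[[rg]] <- fv
  }
  as_tibble(as.list(unlist(cols, use.names = FALSE) |>
                      setNames(unlist(lapply(cols, names)))))
}

#' Extract features for a whole cohort
#'
#' Clusters each patient's sequences into `k` habitats and extracts the
#' six-region feature set, returning a patients-by-features table.
#'
#' @param cohort an `mri_cohort` (patients must expose `t2w`, `dwi`, `voi`,
#'   `voi_dwi`).
#' @param k habitats per sequence (default 2).
#' @param config a [feature_config()].
#' @param seed root seed for the habitat clustering.
#' @return tibble with `patient_id`, `grade`, then feature columns named
#'   `region|image_type|class|feature`.
#' @export
extract_cohort_features <- function(cohort, k = 2,
                                    config = feature_config(), seed = 7) {
  rows <- lapply(cohort, function(p) {
    maps <- patient_habitats(p, k = k, seed = seed)
    masks <- list(whole_T2WI = p$voi, whole_DWI = p$voi_dwi)
    for (sq in c("T2WI", "DWI")) {
      hm <- habitat_masks(maps[[sq]])$masks
      for (h in seq_len(k)) {
        nmh <- paste0("habitat", h)
        masks[[paste0(sq, "_", nmh)]] <- if (!is.null(hm[[nmh]])) hm[[nmh]]
        else mask3d(array(0L, dim(p$voi$data)), p$voi$spacing)
      }
    }
    fv <- extract_feature_vector(p$t2w, p$dwi, masks, config)
    dplyr::bind_cols(tibble(patient_id = p$id, grade = p$grade), fv)
  })
  dplyr::bind_rows(rows)
}
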