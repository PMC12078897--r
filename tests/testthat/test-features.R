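test_that("discretization follows fixed-bin-width arithmetic", {
  v <- tiny_volume(0:99, c(10, 10, 1))
  m <- full_mask(c(10, 10, 1))
  q <- discretize(v, m, 25)
  expect_equal(q$n_levels, 4)
  expect_equal(min(q$levels[q$levels > 0]), 1)
  ## constant region: single level
  vc <- tiny_volume(rep(5, 27), c(3, 3, 3))
  expect_equal(discretize(vc, full_mask(c(3, 3, 3)), 25)$n_levels, 1)
  expect_error(discretize(v, m, 0), "bin_width")
  ## planted two-level phantom recovers its ground truth
  v2 <- tiny_volume(rep(c(10, 40), 50), c(10, 10, 1))
  expect_equal(discretize(v2, m, 25)$n_levels, 2)
})

test_that("first-order features have their closed forms on constant data", {
  n <- 27; cval <- 4
  v <- tiny_volume(rep(cval, n), c(3, 3, 3))
  fo <- first_order_features(v, full_mask(c(3, 3, 3)))
  expect_equal(unname(fo["Mean"]), cval)
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Energy"]), n * cval^2)
  expect_equal(unname(fo["Skewness"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Entropy"]), 0)
})

test_that("skewness vanishes for symmetric data and responds to affine maps", {
  set.seed(3)
  x <- rnorm(4000)
  v <- tiny_volume(x, c(20, 20, 10))
  m <- full_mask(c(20, 20, 10))
  fo <- first_order_features(v, m)
  expect_lt(abs(fo[["Skewness"]]), 0.1)
  ## Mean is affine-equivariant; Skewness is shift/scale-invariant
  v2 <- v; v2$data <- 3 * v$data + 10
  fo2 <- first_order_features(v2, m)
  expect_equal(fo2[["Mean"]], 3 * fo[["Mean"]] + 10)
  expect_equal(fo2[["Skewness"]], fo[["Skewness"]], tolerance = 1e-8)
})

test_that("shape features match the cube oracle", {
  arr <- array(0L, c(12, 12, 12))
  arr[2:11, 2:11, 2:11] <- 1L
  m <- mask3d(arr, spacing = c(1, 1, 1))
  sf <- shape_features(m)
  expect_equal(sf[["VoxelVolume"]], 1000)
  expect_equal(sf[["SurfaceArea"]], 600)
  expect_equal(sf[["Sphericity"]], pi^(1 / 3) * (6 * 1000)^(2 / 3) / 600)
  expect_equal(sf[["Maximum3DDiameter"]], sqrt(3 * 81))
  expect_equal(sf[["Maximum2DDiameterSlice"]], sqrt(2 * 81))
  expect_equal(sf[["Elongation"]], 1)
  expect_equal(sf[["Flatness"]], 1)

  single <- mask3d(array(c(1L, rep(0L, 26)), c(3, 3, 3)))
  expect_warning(sfs <- shape_features(single), "undefined")
  expect_true(all(is.na(sfs)))
})

test_that("the filter bank yields 21 named image types with the right limits", {
  p <- cached_patient(7)
  bank <- build_image_types(p$t2w)
  expect_length(bank, 21)
  expect_named(bank)
  expect_equal(names(bank)[1], "original")

  cv <- volume3d(array(7, c(12, 12, 12)))
  cb <- build_image_types(cv)
  expect_lt(max(abs(cb$log_sigma_2_mm$data)), 1e-8)
  expect_equal(max(abs(cb$gradient$data)), 0)
  expect_equal(cb$wavelet_LLL$data, cv$data)  # lowpass preserves constants
  expect_error(build_image_types(volume3d(array(1:27, c(3, 3, 3))),
                                 log_sigmas_mm = 4), "extent")
})

test_that("region extraction reproduces the printed feature budget", {
  p <- cached_patient(7)
  fv <- extract_region_features(p$t2w, p$voi, feature_config("all"))
  expect_length(fv, 1904)
  expect_false(any(duplicated(names(fv))))
  cls <- vapply(strsplit(names(fv), "|", fixed = TRUE), `[`, "", 2)
  expect_equal(unname(table(cls)[c("firstorder", "shape", "glcm", "glrlm",
                                   "glszm", "gldm", "ngtdm")]),
               c(378L, 14L, 441L, 336L, 336L, 294L, 105L),
               ignore_attr = TRUE)
  expect_true(all(is.finite(fv)))
  ## counts mirror feature_class_counts
  expect_equal(unname(feature_class_counts(feature_config("all"))[["total"]]),
               1904L)
})

test_that("extraction is deterministic and consistent with plain statistics", {
  p <- cached_patient(7)
  cfgf <- feature_config("original")
  masks <- list(whole_T2WI = p$voi, whole_DWI = p$voi_dwi,
                T2WI_habitat1 = p$voi, T2WI_habitat2 = p$voi,
                DWI_habitat1 = p$voi_dwi, DWI_habitat2 = p$voi_dwi)
  a <- extract_feature_vector(p$t2w, p$dwi, masks, cfgf)
  b <- extract_feature_vector(p$t2w, p$dwi, masks, cfgf)
  expect_identical(a, b)
  expect_equal(a[["whole_T2WI|original|firstorder|Mean"]],
               mean(mask_values(p$t2w, p$voi)))
})

test_that("empty regions are emitted as missing with a warning", {
  p <- cached_patient(7)
  empty <- mask3d(array(0L, dim(p$voi$data)), p$voi$spacing)
  masks <- list(whole_T2WI = p$voi, whole_DWI = p$voi_dwi,
                T2WI_habitat1 = p$voi, T2WI_habitat2 = empty,
                DWI_habitat1 = p$voi_dwi, DWI_habitat2 = p$voi_dwi)
  expect_warning(
    fv <- extract_feature_vector(p$t2w, p$dwi, masks, feature_config("original")),
    "empty"
  )
  h2 <- grep("^T2WI_habitat2", names(fv), value = TRUE)
  expect_true(all(is.na(unlist(fv[h2]))))
  h1 <- grep("^T2WI_habitat1", names(fv), value = TRUE)
  expect_false(anyNA(unlist(fv[h1])))
})
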