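make_bias_phantom <- function(dims = c(24, 24, 20), amp = 0.3, seed = 1) {
  set.seed(seed)
  base <- array(100 + rnorm(prod(dims), 0, 2), dims)
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  xn <- (g$x - (dims[1] + 1) / 2) / dims[1]
  yn <- (g$y - (dims[2] + 1) / 2) / dims[2]
  zn <- (g$z - (dims[3] + 1) / 2) / dims[3]
  q <- array(xn^2 + 0.5 * yn^2 - xn * zn, dims)
  q <- q / max(abs(q))
  list(clean = volume3d(base, c(1.5, 1.5, 1.5)),
       biased = volume3d(base * (1 + amp * q), c(1.5, 1.5, 1.5)),
       field = 1 + amp * q)
}

test_that("bias correction removes a planted quadratic field", {
  ph <- make_bias_phantom(amp = 0.3)
  cv <- function(x) sd(as.vector(x)) / mean(as.vector(x))
  out <- correct_bias(ph$biased)
  expect_lt(cv(out$corrected$data), 0.5 * cv(ph$biased$data))
  ## within-mask mean preserved within 1%
  expect_lt(abs(mean(out$corrected$data) / mean(ph$biased$data) - 1), 0.01)
})

test_that("bias correction is a near-identity on bias-free input", {
  p <- cached_patient(3)
  out <- correct_bias(p$t2w)
  expect_lt(max(abs(out$corrected$data / p$t2w$data - 1)), 0.02)
})

test_that("constant volumes pass through bias correction unchanged", {
  v <- volume3d(array(50, c(8, 8, 8)))
  out <- correct_bias(v)
  expect_equal(out$corrected$data, v$data)
  bad <- volume3d(array(c(-1, rep(2, 511)), c(8, 8, 8)))
  expect_error(correct_bias(bad), "positive")
})

test_that("isotropic resampling preserves extent and mask labels", {
  v <- volume3d(array(rnorm(20^3), c(20, 20, 20)), spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(v, 1), v)  # identity case

  arr <- array(0L, c(20, 20, 20)); arr[3:18, 3:18, 3:18] <- 1L
  m <- mask3d(arr, spacing = c(2, 2, 2))
  m1 <- resample_isotropic(m, 1)
  expect_true(all(dim(m1$data) >= 39) && all(dim(m1$data) <= 41))
  expect_true(all(m1$data %in% c(0L, 1L)))
  vol_before <- sum(m$data) * voxel_volume(m)
  vol_after <- sum(m1$data) * voxel_volume(m1)
  expect_lt(abs(vol_after / vol_before - 1), 0.05)
})

test_that("histogram standardization aligns, is monotone and idempotent", {
  co <- generate_cohort(cohort_config(n_patients = 3, seed = 9))
  vols <- lapply(co, function(p) p$t2w)
  model <- learn_landmarks(vols)
  expect_true(all(diff(model$mean_landmarks) > 0))

  ## volumes differing by a global affine map agree after standardization
  va <- vols[[1]]
  vb <- va; vb$data <- 2 * va$data + 50
  m2 <- learn_landmarks(list(va, vb))
  qa <- quantile(standardize_histogram(va, m2)$data, seq(0.1, 0.9, 0.1))
  qb <- quantile(standardize_histogram(vb, m2)$data, seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(qa - qb)), 1e-8)

  s1 <- standardize_histogram(va, model)
  s2 <- standardize_histogram(s1, model)
  expect_lt(max(abs(s1$data - s2$data)), 1e-6)

  expect_error(learn_landmarks(list(va, volume3d(array(1, c(4, 4, 4))))),
               "constant")
})

test_that("registration recovers identity and planted translations", {
  p <- cached_patient(5)
  reg0 <- register_volumes(p$t2w, p$t2w)
  expect_lt(sqrt(sum(reg0$transform$translation^2)), 0.1)

  cfg <- cohort_config(n_patients = 1, seed = 5,
                       misalignment = list(shift = c(3, 0, 0),
                                           warp_amplitude = 0))
  pa <- apply_artifacts(generate_cohort(cfg)[[1]], cfg)
  reg <- register_volumes(pa$dwi, pa$t2w)
  err <- reg$transform$translation - c(3, 0, 0)
  expect_lt(sqrt(sum(err^2)), 0.5)
})

test_that("deformable registration restores VOI overlap after shift + warp", {
  cfg <- cohort_config(n_patients = 1, seed = 5)  # default 3 mm shift + warp
  pa <- apply_artifacts(generate_cohort(cfg)[[1]], cfg)
  before <- dice_overlap(pa$voi_dwi, pa$voi)
  expect_lte(before, 0.8)
  reg <- register_volumes(pa$dwi, pa$t2w, deformable = TRUE)
  after <- dice_overlap(apply_transform(pa$voi_dwi, reg$transform), pa$voi)
  expect_gte(after, 0.95)
})

test_that("the preprocessing chain is deterministic", {
  cfg <- cohort_config(n_patients = 2, seed = 17)
  co <- generate_cohort(cfg)
  arts <- lapply(co, apply_artifacts, config = cfg)
  lms <- list(T2WI = learn_landmarks(lapply(arts, `[[`, "t2w")),
              DWI = learn_landmarks(lapply(arts, `[[`, "dwi")))
  r1 <- preprocess_patient(arts[[1]], landmarks = lms, spacing = NULL,
                           deformable = FALSE)
  r2 <- preprocess_patient(arts[[1]], landmarks = lms, spacing = NULL,
                           deformable = FALSE)
  expect_identical(r1$t2w$data, r2$t2w$data)
  expect_identical(r1$dwi$data, r2$dwi$data)
})
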