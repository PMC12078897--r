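test_that("cohort generation is deterministic and respects prevalence", {
  cfg <- cohort_config(n_patients = 40, prevalence_high = 0.5, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  grades <- vapply(a, function(p) p$grade, integer(1))
  expect_gt(sum(grades), 10)   # ~20 expected at prevalence 0.5
  expect_lt(sum(grades), 30)
  for (p in a) {
    expect_gt(sum(p$voi$data != 0L), 0)
    ## VOI strictly inside the volume bounds
    idx <- mask_indices(p$voi)
    expect_true(all(idx > 1) && all(sweep(idx, 2, dim(p$voi$data), "<")))
    ## habitat map labels exactly the VOI voxels
    expect_identical(p$true_habitat_map$T2WI$data != 0L, p$voi$data != 0L)
  }
})

test_that("config validation rejects bad fractions and ordering", {
  expect_error(cohort_config(prevalence_high = 1.2), "prevalence")
  expect_error(cohort_config(habitat_fraction_low = c(0.5, 0.6)), "summing")
  expect_error(
    cohort_config(intensity_means = list(T2WI = c(100, 200),
                                         DWI = c(250, 140))),
    "habitat1"
  )
})

test_that("planted habitat fractions are recovered in the cohort mean", {
  cfg <- cohort_config(n_patients = 40, prevalence_high = 0.5,
                       habitat_fraction_high = c(0.5, 0.5),
                       habitat_fraction_low = c(0.9, 0.1), seed = 21)
  co <- generate_cohort(cfg)
  high <- Filter(function(p) p$grade == 1L, co)
  emp <- vapply(high, function(p) {
    mean(p$true_habitat_map$T2WI$data[p$voi$data != 0L] == 2L)
  }, numeric(1))
  expect_lt(abs(mean(emp) - 0.5), 0.05)
})

test_that("within-VOI intensities are bimodal when habitats separate", {
  ## with habitat means >= 3 SD apart, a 2-cluster split explains most of
  ## the within-VOI variance (a k-means analogue of a dip check)
  p <- cached_patient(7)
  x <- mask_values(p$t2w, p$voi)
  km1 <- sum((x - mean(x))^2)
  km2 <- min(stats::kmeans(x, 2, nstart = 5)$tot.withinss)
  expect_lt(km2 / km1, 0.35)
})

test_that("artifacts leave volumes unchanged in the identity case", {
  cfg <- cohort_config(n_patients = 1, bias_amplitude = 0,
                       misalignment = list(shift = c(0, 0, 0),
                                           warp_amplitude = 0), seed = 3)
  p0 <- generate_cohort(cfg)[[1]]
  p1 <- apply_artifacts(p0, cfg)
  expect_equal(p1$t2w$data, p0$t2w$data)
  expect_equal(p1$dwi$data, p0$dwi$data)
  expect_identical(p1$voi_dwi$data, p0$voi_dwi$data)
})

test_that("bias increases within-VOI CV and shifts move the DWI VOI", {
  cfg <- cohort_config(n_patients = 1, bias_amplitude = 0.3,
                       misalignment = list(shift = c(3, 0, 0),
                                           warp_amplitude = 0), seed = 5)
  p0 <- generate_cohort(cfg)[[1]]
  p1 <- apply_artifacts(p0, cfg)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(mask_values(p1$t2w, p1$voi)), cv(mask_values(p0$t2w, p0$voi)))
  com_shift <- mask_center_of_mass(p1$voi_dwi) - mask_center_of_mass(p0$voi)
  expect_lt(abs(com_shift[1] - 3), 0.5)
  expect_lt(max(abs(com_shift[2:3])), 0.5)
  expect_error(
    apply_artifacts(p0, modifyList(cfg, list(bias_amplitude = -1))),
    "amplitude"
  )
})

test_that("reader tables reproduce planted agreement levels", {
  co <- generate_cohort(cohort_config(n_patients = 30, seed = 11))
  perfect <- generate_reader_tables(co, continuous_noise_sd = 0,
                                    flip_prob = 0, seed = 1)
  expect_equal(cohens_kappa(perfect$categorical$reader1,
                            perfect$categorical$reader2), 1)
  expect_equal(icc_two_way(perfect$continuous[, c("reader1", "reader2")]), 1)

  ## flip probability 0.5 with two balanced classes: chance agreement
  co2 <- generate_cohort(cohort_config(n_patients = 400, seed = 12))
  chance <- generate_reader_tables(co2, flip_prob = 0.5, seed = 2)
  kap <- cohens_kappa(chance$categorical$reader1, chance$categorical$reader2)
  expect_lt(abs(kap), 0.15)
})

test_that("ICC matches its closed form when reader noise equals true sd", {
  co <- generate_cohort(cohort_config(n_patients = 500, seed = 13))
  truth_sd <- sd(vapply(co, function(p) {
    sum(p$voi$data != 0L) * voxel_volume(p$voi) / 1000
  }, numeric(1)))
  rt <- generate_reader_tables(co, continuous_noise_sd = truth_sd, seed = 3)
  icc <- icc_two_way(rt$continuous[, c("reader1", "reader2")])
  expect_lt(abs(icc - 0.5), 0.08)
})
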