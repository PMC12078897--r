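## Every texture-matrix family is checked against an independent
## brute-force voxel-loop oracle on small random grids (all dims <= 4 x 4 x 3,
## 3 gray levels, random masked-out holes) plus hand-built structured cases.

dims_pool <- list(c(2, 2, 1), c(3, 3, 1), c(3, 2, 2), c(4, 3, 2), c(4, 4, 3))

test_that("GLCM matrices equal exhaustive pair counting", {
  set.seed(101)
  dirs <- habitomics:::unique_directions_13()
  for (rep in 1:25) {
    q <- random_quantized_grid(dims_pool[[(rep %% 5) + 1]], ng = 3)
    for (r in seq_len(nrow(dirs))) {
      expect_equal(glcm_matrix(q, 3, dirs[r, ]), bf_glcm(q, 3, dirs[r, ]),
                   ignore_attr = TRUE)
    }
  }
  ## structured checkerboard slab
  q <- array(c(1L, 2L, 2L, 1L, 1L, 2L), c(3, 2, 1))
  for (r in seq_len(nrow(dirs))) {
    expect_equal(glcm_matrix(q, 2, dirs[r, ]), bf_glcm(q, 2, dirs[r, ]),
                 ignore_attr = TRUE)
  }
})

test_that("single-level regions give degenerate GLCM features", {
  q <- array(1L, c(3, 3, 2))
  f <- glcm_features(q, 1)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["MaximumProbability"]], 1)
  expect_true(is.na(f[["Correlation"]]))
})

test_that("GLRLM matrices equal brute-force run walking", {
  set.seed(202)
  dirs <- habitomics:::unique_directions_13()
  for (rep in 1:25) {
    q <- random_quantized_grid(dims_pool[[(rep %% 5) + 1]], ng = 3)
    for (r in seq_len(nrow(dirs))) {
      a <- glrlm_matrix(q, 3, dirs[r, ])
      b <- bf_glrlm(q, 3, dirs[r, ])
      mx <- max(ncol(a), ncol(b))
      pad <- function(m) cbind(m, matrix(0, nrow(m), mx - ncol(m)))
      expect_equal(pad(a), pad(b), ignore_attr = TRUE)
    }
  }
})

test_that("GLRLM run accounting matches the hand-enumerated line example", {
  q <- array(c(1L, 1L, 2L, 2L, 2L), c(1, 1, 5))
  m <- glrlm_matrix(q, 2, c(0, 0, 1))
  expect_equal(m[1, 2], 1)  # one run of level 1, length 2
  expect_equal(m[2, 3], 1)  # one run of level 2, length 3
  expect_equal(sum(m), 2)
  f <- habitomics:::glrlm_features_one(m, np = 5)
  expect_equal(f[["RunPercentage"]], 2 / 5)
})

test_that("GLSZM zones equal flood-fill enumeration", {
  set.seed(303)
  for (rep in 1:25) {
    q <- random_quantized_grid(dims_pool[[(rep %% 5) + 1]], ng = 3)
    a <- glszm_matrix(q, 3)
    b <- bf_glszm(q, 3)
    mx <- max(ncol(a), ncol(b))
    pad <- function(m) cbind(m, matrix(0, nrow(m), mx - ncol(m)))
    expect_equal(pad(a), pad(b), ignore_attr = TRUE)
  }
})

test_that("GLDM matrices equal per-voxel neighbor counting", {
  set.seed(404)
  for (rep in 1:25) {
    q <- random_quantized_grid(dims_pool[[(rep %% 5) + 1]], ng = 3)
    expect_equal(gldm_matrix(q, 3), bf_gldm(q, 3), ignore_attr = TRUE)
  }
  ## nonzero tolerance changes the dependence counts consistently
  q <- random_quantized_grid(c(4, 4, 3), ng = 3)
  expect_equal(gldm_matrix(q, 3, alpha = 1), bf_gldm(q, 3, alpha = 1),
               ignore_attr = TRUE)
})

test_that("NGTDM ingredients equal per-voxel neighborhood means", {
  set.seed(505)
  for (rep in 1:25) {
    q <- random_quantized_grid(dims_pool[[(rep %% 5) + 1]], ng = 3)
    a <- ngtdm_stats(q, 3)
    b <- bf_ngtdm(q, 3)
    expect_equal(a$n, b$n, ignore_attr = TRUE)
    expect_equal(a$s, b$s, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(a$n_valid, b$n_valid)
  }
})

test_that("texture features are invariant to voxel storage order", {
  ## relabeling the same geometry through array transposition leaves
  ## direction-averaged features unchanged
  set.seed(9)
  q <- random_quantized_grid(c(4, 4, 4), ng = 3, p_hole = 0.1)
  qt <- aperm(q, c(2, 1, 3))
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  gldm_features, ngtdm_features)) {
    expect_equal(fn(q, 3), fn(qt, 3), tolerance = 1e-10)
  }
})
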