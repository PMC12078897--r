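test_that("the stratified split preserves grade proportions and is stable", {
  records <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:100),
    grade = rep(c(1L, 0L), c(40, 60))
  )
  s1 <- split_cohort(records, prop = 0.8, seed = 5)
  s2 <- split_cohort(records, prop = 0.8, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sum(s1$cohort == "training"), 80)
  expect_equal(sum(s1$cohort == "training" & s1$grade == 1L), 32)

  ## stratum proportions survive label permutation
  set.seed(1)
  records2 <- records[sample(100), ]
  s3 <- split_cohort(records2, prop = 0.8, seed = 5)
  expect_equal(sum(s3$cohort == "training" & s3$grade == 1L), 32)
})

test_that("the chi-square filter reproduces the 2x2 hand computation", {
  ## hi/lo split realizing the table [[20,5],[5,20]]
  labels <- c(rep(1, 20), rep(0, 5), rep(1, 5), rep(0, 20))
  x <- c(rep(1, 25), rep(0, 25))
  res <- chi_square_filter(data.frame(f = x), labels)
  expect_equal(res$statistic, 18, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_true(res$passed)

  ## a feature identical to the label is retained with p ~ 0
  y <- rep(c(0, 1), 30)
  res2 <- chi_square_filter(data.frame(f = y + 10), y)
  expect_true(res2$passed)
  expect_lt(res2$p_value, 1e-10)

  ## zero-variance features are excluded with a warning
  expect_warning(
    res3 <- chi_square_filter(data.frame(f = rep(1, 60)), y),
    "zero-variance"
  )
  expect_false(res3$passed)
})

test_that("the chi-square filter holds its type-I error for null features", {
  set.seed(7)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  reps <- 400
  kept <- vapply(seq_len(reps), function(i) {
    chi_square_filter(data.frame(f = rnorm(n)), y)$passed
  }, logical(1))
  expect_lt(abs(mean(kept) - 0.05), 0.03)
})

test_that("LASSO recovers a planted effect among noise features", {
  set.seed(11)
  hits <- 0L
  for (s in 1:10) {
    n <- 300
    x <- matrix(rnorm(n * 21), n, 21)
    colnames(x) <- paste0("f", 1:21)
    eta <- 2 * x[, 1]
    y <- rbinom(n, 1, plogis(eta))
    sel <- lasso_select(as.data.frame(x), y, seed = s)
    hits <- hits + ("f1" %in% sel$selected)
  }
  expect_gte(hits, 9)
})

test_that("LASSO selection is invariant to affine feature rescaling", {
  set.seed(13)
  n <- 120
  x <- matrix(rnorm(n * 6), n, 6)
  colnames(x) <- paste0("f", 1:6)
  y <- rbinom(n, 1, plogis(1.5 * x[, 2] - x[, 5]))
  a <- lasso_select(as.data.frame(x), y, seed = 3)
  xs <- sweep(sweep(x, 2, c(10, 0.1, 3, 7, 0.5, 2), `*`), 2, 1:6, `+`)
  colnames(xs) <- colnames(x)
  b <- lasso_select(as.data.frame(xs), y, seed = 3)
  expect_setequal(a$selected, b$selected)
})

test_that("subregion logistic fits match closed-form odds ratios", {
  ## single binary feature with counts [[40,10],[10,40]] -> OR = 16
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  fit <- fit_subregion_model(data.frame(f = x), y, "f", region = "test")
  or_raw <- exp(fit$coefficients[["f"]] / fit$scale[["f"]])
  expect_equal(or_raw, 16, tolerance = 1e-6)
  p <- predict(fit, data.frame(f = c(0, 1)))
  expect_true(all(p > 0 & p < 1))

  ## a zero-variance feature reduces to the base-rate model
  y2 <- rep(c(1, 0, 0, 0, 1, 0, 1, 0, 0, 0), 10)  # 30% positives
  fit2 <- fit_subregion_model(data.frame(f = rep(1, 100)), y2, "f")
  expect_equal(unname(predict(fit2, data.frame(f = rep(1, 3)))),
               rep(0.3, 3), tolerance = 1e-6)
  expect_error(fit_subregion_model(data.frame(f = x), y, character(0)),
               "at least one")
})

test_that("the ITH index is the mean of the chosen subset probabilities", {
  probs <- c(T2WI_habitat1 = 0.8, T2WI_habitat2 = 0.1,
             DWI_habitat1 = 0.3, DWI_habitat2 = 0.4)
  expect_equal(as.numeric(ith_index(probs, c("T2WI_habitat1", "DWI_habitat2"))),
               0.6)
  expect_equal(as.numeric(ith_index(probs, "DWI_habitat1")), 0.3)
  expect_equal(as.numeric(ith_index(rep(0.42, 4) |>
                                      setNames(names(probs)), names(probs))),
               0.42)
  ## permutation invariance and bounds
  s1 <- ith_index(probs, c("T2WI_habitat1", "DWI_habitat1", "DWI_habitat2"))
  s2 <- ith_index(probs, c("DWI_habitat2", "T2WI_habitat1", "DWI_habitat1"))
  expect_equal(as.numeric(s1), as.numeric(s2))
  expect_true(s1 >= 0 && s1 <= 1)
  ## missing members are dropped and flagged
  probs[1] <- NA
  out <- ith_index(probs, c("T2WI_habitat1", "DWI_habitat2"))
  expect_equal(as.numeric(out), 0.4)
  expect_true(attr(out, "incomplete"))
  expect_error(ith_index(probs, "nope"), "without probabilities")
})

test_that("candidate enumeration yields the 13 admissible subsets", {
  cands <- enumerate_candidates()
  expect_length(cands, 13)
  keys <- vapply(cands, function(cb) paste(sort(cb), collapse = "+"),
                 character(1))
  expect_false("DWI_habitat1+DWI_habitat2" %in% keys)
  expect_false("T2WI_habitat1+T2WI_habitat2" %in% keys)
  expect_true("DWI_habitat2+T2WI_habitat1" %in% keys)
  expect_equal(sum(lengths(cands) == 1), 4)
  expect_equal(sum(lengths(cands) == 2), 4)
  expect_equal(sum(lengths(cands) == 3), 4)
  expect_equal(sum(lengths(cands) == 4), 1)
})

test_that("habitat-model selection picks the dominating candidate", {
  set.seed(5)
  n <- 120
  y <- rep(c(0L, 1L), n / 2)
  is_train <- rep(c(TRUE, FALSE), c(80, 40))
  ## only T2WI_habitat1 is informative -> its singleton dominates
  probs <- tibble::tibble(
    T2WI_habitat1 = plogis(3 * (y - 0.5) + rnorm(n, 0, 0.5)),
    T2WI_habitat2 = runif(n),
    DWI_habitat1 = runif(n),
    DWI_habitat2 = runif(n)
  )
  hm <- suppressWarnings(select_habitat_model(probs, y, is_train))
  expect_true("T2WI_habitat1" %in% hm$subset)
  expect_equal(nrow(hm$candidates), 13)

  ## exact ties break toward the smaller subset
  flat <- tibble::tibble(T2WI_habitat1 = probs$T2WI_habitat1,
                         T2WI_habitat2 = probs$T2WI_habitat1,
                         DWI_habitat1 = probs$T2WI_habitat1,
                         DWI_habitat2 = probs$T2WI_habitat1)
  hm2 <- suppressWarnings(select_habitat_model(flat, y, is_train))
  expect_length(hm2$subset, 1)
})

test_that("covariate screening matches the closed-form 2x2 odds ratio", {
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  res <- univariable_multivariable_lr(tibble::tibble(grade = y, margin = x))
  expect_equal(res$table$or, 16, tolerance = 1e-4)
  expect_gt(res$table$ci_low, 1)
  expect_true("margin" %in% res$retained)
})

test_that("pure-noise covariates are retained at about the alpha rate", {
  set.seed(31)
  n <- 200
  reps <- 200
  kept <- vapply(seq_len(reps), function(i) {
    y <- rbinom(n, 1, 0.5)
    res <- univariable_multivariable_lr(
      tibble::tibble(grade = y, v = rbinom(n, 1, 0.4))
    )
    length(res$retained) > 0
  }, logical(1))
  expect_lt(abs(mean(kept) - 0.05), 0.04)
})

test_that("the generator's planted covariate effects are recoverable", {
  hits <- 0L
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(n_patients = 160, seed = 100 + s))
    covs <- cohort_covariates(co)
    res <- univariable_multivariable_lr(covs[, setdiff(names(covs),
                                                       "patient_id")])
    hits <- hits + all(c("tumor_margin_infiltrative", "t2wi_targetoid") %in%
                         res$retained)
  }
  expect_gte(hits, 4)
})

test_that("the seven final models are fitted on the stated block unions", {
  set.seed(17)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  blocks <- list(
    clinlabimag = data.frame(c1 = rbinom(n, 1, 0.5), c2 = rbinom(n, 1, 0.3)),
    radiomics = data.frame(r1 = rnorm(n) + y, r2 = rnorm(n), r3 = rnorm(n)),
    habitat = data.frame(ith_index = plogis(y + rnorm(n)))
  )
  bundle <- fit_final_models(blocks, y)
  expect_named(bundle$models,
               c("ClinLabImag", "Radiomics", "Habitat",
                 "ClinLabImag-Radiomics", "ClinLabImag-Habitat",
                 "Radiomics-Habitat", "Combined"))
  expect_length(bundle$models$Combined$coefficients, 2 + 3 + 1)
  expect_length(bundle$thresholds, 7)
  preds <- predict_bundle(bundle, blocks)
  expect_true(all(vapply(preds, function(p) all(p > 0 & p < 1), logical(1))))

  ## an empty block skips the dependent models with a warning
  blocks$clinlabimag <- data.frame()[seq_len(n), , drop = FALSE]
  expect_warning(b2 <- fit_final_models(blocks, y), "skipped")
  expect_false("ClinLabImag" %in% names(b2$models))
  expect_true("Radiomics-Habitat" %in% names(b2$models))
})

test_that("no validation row leaks into selection or standardization", {
  ## chi-square medians, LASSO scaling and thresholds come from training
  ## rows only: perturbing validation rows must not change them
  set.seed(23)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  x <- data.frame(a = rnorm(n) + y, b = rnorm(n), c = rnorm(n))
  is_train <- rep(c(TRUE, FALSE), c(45, 15))
  sel1 <- lasso_select(x[is_train, ], y[is_train], seed = 2)
  x2 <- x; x2[!is_train, ] <- x2[!is_train, ] * 100 + 7
  sel2 <- lasso_select(x2[is_train, ], y[is_train], seed = 2)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$center, sel2$center)
})
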