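test_that("AUC matches exhaustive pair counting on hand cases", {
  expect_equal(roc_auc_delong(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc_delong(c(0.9, 0.6, 0.8, 0.7), c(1, 1, 0, 0))$auc, 0.5)
  expect_error(roc_auc_delong(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals brute-force concordance on random score sets", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(rnorm(n), 2))  # rounded scores force ties
    a <- roc_auc_delong(s, y)
    expect_equal(a$auc, bf_auc(s, y), tolerance = 1e-12)
    expect_true(a$ci95[1] <= a$auc && a$auc <= a$ci95[2])
    expect_true(all(a$ci95 >= 0 & a$ci95 <= 1))
  }
})

test_that("DeLong AUC and variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- rbinom(120, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- rnorm(120) + y
  ours <- roc_auc_delong(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(ours$ci95, as.numeric(ci[c(1, 3)]), tolerance = 1e-4)
})

test_that("the DeLong test is symmetric, self-null, and powered", {
  set.seed(5)
  y <- rbinom(200, 1, 0.5); y[1:2] <- c(0, 1)
  a <- rnorm(200) + y
  b <- rnorm(200)
  expect_equal(delong_test(a, a, y)$p_value, 1)
  expect_equal(delong_test(a, b, y)$p_value, delong_test(b, a, y)$p_value)

  set.seed(6)
  sig <- vapply(1:20, function(i) {
    y <- rbinom(500, 1, 0.5); y[1:2] <- c(0, 1)
    delong_test(rnorm(500) + 1.5 * y, rnorm(500), y)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("DeLong CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(8)
  width <- vapply(c(100, 400), function(n) {
    mean(vapply(1:30, function(i) {
      y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
      a <- roc_auc_delong(rnorm(n) + y, y)
      diff(a$ci95)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(width[2] / width[1], 0.65)  # ideal ratio 0.5
})

test_that("threshold metrics match the hand-built confusion matrix", {
  ## TP = 9, FN = 1, TN = 8, FP = 2
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.8, 2))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- threshold_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 9 / 11)

  low <- threshold_metrics(scores, labels, threshold = 0)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  high <- threshold_metrics(scores, labels, threshold = 2)
  expect_true(is.na(high$precision))
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
})

test_that("the Youden threshold maximizes sensitivity + specificity", {
  scores <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(youden_threshold(scores, labels), 0.7)
})

test_that("calibration bins track the truth for calibrated predictions", {
  set.seed(44)
  p <- runif(4000)
  y <- rbinom(4000, 1, p)
  cal <- calibration_curve(p, y, n_bins = 10)
  expect_true(all(abs(cal$observed - cal$mean_predicted) <
                    3 * sqrt(0.25 / cal$n)))
  expect_error(calibration_curve(c(-0.2, 0.5), c(0, 1)), "probabilities")
})

test_that("decision-curve references have their closed forms", {
  set.seed(45)
  p <- runif(500)
  y <- rbinom(500, 1, p)
  dc <- decision_curve(p, y)
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y)
  ## at pt = prevalence the treat-all net benefit crosses zero
  at_prev <- prev - (1 - prev) * prev / (1 - prev)
  expect_equal(at_prev, 0)
  ## a better-discriminating model dominates over mid-range thresholds
  noisy <- pmin(pmax(p + rnorm(500, 0, 0.4), 0.001), 0.999)
  dc2 <- decision_curve(noisy, y)
  mid <- dc$threshold >= 0.3 & dc$threshold <= 0.7
  expect_gte(mean(dc$net_benefit[mid] - dc2$net_benefit[mid]), 0)
})

test_that("linear Shapley values are exact for logistic models", {
  set.seed(55)
  n <- 150
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(X$a - 0.5 * X$b))
  fit <- habitomics:::fit_logistic(X, y)
  rep <- linear_shap(fit, X, X)
  eta <- predict(fit, X, type = "link")
  expect_lt(max(abs(rowSums(rep$values) + rep$base - eta)), 1e-8)

  ## evaluating at the background mean zeroes every attribution
  mu <- as.data.frame(as.list(colMeans(X)))
  rep0 <- linear_shap(fit, mu, X)
  expect_lt(max(abs(rep0$values)), 1e-10)

  ## a zero-coefficient feature receives zero attribution
  fit0 <- fit
  fit0$coefficients[["c"]] <- 0
  repz <- linear_shap(fit0, X, X)
  expect_true(all(repz$values[, "c"] == 0))
  expect_error(linear_shap(fit, X, X[, 1:2]), "missing")
})

test_that("kappa and ICC match hand arithmetic and degenerate cases", {
  expect_equal(cohens_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_warning(k <- cohens_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_true(is.na(k))

  ratings <- cbind(1:10, 1:10)
  expect_equal(icc_two_way(ratings), 1)
  expect_error(icc_two_way(matrix(1:10, ncol = 1)), "2 raters")
})

test_that("cohort comparison tests dispatch by type and expected counts", {
  set.seed(66)
  n <- 40
  g <- rep(c(0, 1), each = n / 2)
  rec <- tibble::tibble(
    age = rnorm(n, 60, 8),
    binary_common = rbinom(n, 1, 0.5),
    rare = c(rbinom(n / 2, 1, 0.05), rbinom(n / 2, 1, 0.08)),
    constant = rep(1, n)
  )
  out <- cohort_comparison_tests(rec, g)
  expect_equal(out$test[out$variable == "age"], "mann-whitney")
  expect_true(out$test[out$variable == "rare"] %in% c("fisher"))
  expect_true(is.na(out$p_value[out$variable == "constant"]))

  ## identical groups: exact tests report p = 1
  rec2 <- tibble::tibble(v = rep(c(0, 1), n / 2))
  out2 <- cohort_comparison_tests(rec2, g)
  expect_gt(out2$p_value, 0.9)
})

test_that("Fisher's exact p matches hypergeometric enumeration", {
  tab <- matrix(c(8, 1, 2, 9), 2)
  rec <- tibble::tibble(v = c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9)))
  g <- rep(c(0, 1), each = 10)
  out <- cohort_comparison_tests(rec, g)
  ## enumerate all tables with the observed margins
  m <- 10; k <- 9  # row 1 total of v == 1, column totals 10/10
  probs <- dhyper(0:9, 9, 11, 10)
  p0 <- dhyper(8, 9, 11, 10)
  oracle <- sum(probs[probs <= p0 + 1e-12])
  expect_equal(out$p_value, oracle, tolerance = 1e-10)
})
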