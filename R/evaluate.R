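#' AUC with DeLong variance and confidence interval
#'
#' Mann-Whitney AUC with midrank tie handling and the DeLong
#' structural-components variance estimator; the normal-approximation 95%
#' interval is truncated to `[0, 1]`.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary labels (0/1), both classes present.
#' @return list with `auc`, `ci95` (length 2), `var`.
#' @export
roc_auc_delong <- function(scores, labels) {
  comp <- delong_components(scores, labels)
  auc <- comp$auc
  v <- var(comp$v10) / comp$m + var(comp$v01) / comp$n
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1.96, 1.96) * se, 0), 1)
  list(auc = auc, ci95 = ci, var = v)
}

## DeLong structural components: v10 over positives, v01 over negatives.
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("AUC undefined: both classes must be present.")
  }
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - r_pos) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - r_neg) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided z-test on the difference of two AUCs computed from paired
#' scores on the same patients, using the DeLong covariance of the
#' structural components. Comparing identical score vectors gives p = 1.
#'
#' @param scores_a,scores_b paired numeric predictions.
#' @param labels binary labels (0/1).
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    abort("scores must be paired on identical patients.")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (v < 1e-16) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Training-set Youden threshold
#'
#' @param scores,labels training predictions and binary labels.
#' @return the score cut maximizing sensitivity + specificity - 1 (ties:
#'   lowest threshold).
#' @export
youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    calls <- scores >= t
    sens <- sum(calls & labels == 1L) / sum(labels == 1L)
    spec <- sum(!calls & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' @param scores numeric predictions.
#' @param labels binary labels (0/1).
#' @param threshold decision cut (calls are `scores >= threshold`),
#'   typically the training-set Youden threshold.
#' @return tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `precision` (NA when no positive calls are made).
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  calls <- scores >= threshold
  tp <- sum(calls & labels == 1L); fn <- sum(!calls & labels == 1L)
  tn <- sum(!calls & labels == 0L); fp <- sum(calls & labels == 0L)
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Calibration curve with equal-frequency bins
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels binary outcomes.
#' @param n_bins number of equal-frequency bins (empty bins merge with
#'   their neighbor automatically via unique quantile breaks).
#' @return tibble `bin`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10) {
  if (any(scores < 0 | scores > 1)) {
    abort("calibration requires probabilities in [0, 1].")
  }
  breaks <- unique(quantile(scores, seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3L) breaks <- c(-Inf, median(scores), Inf)
  binf <- cut(scores, breaks, include.lowest = TRUE)
  out <- tibble(
    bin = levels(binf),
    n = as.integer(table(binf)),
    mean_predicted = as.numeric(tapply(scores, binf, mean)),
    observed = as.numeric(tapply(labels, binf, mean))
  )
  out[out$n > 0, , drop = FALSE]
}

#' Decision-curve net benefit
#'
#' Net benefit at threshold probability pt is TP/n - FP/n * pt/(1-pt),
#' evaluated by calling positives at `scores >= pt`; the treat-all and
#' treat-none references are included.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold-probability grid.
#' @return tibble `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  n <- length(labels)
  prev <- mean(labels == 1L)
  rows <- lapply(thresholds, function(pt) {
    calls <- scores >= pt
    tp <- sum(calls & labels == 1L); fp <- sum(calls & labels == 0L)
    w <- pt / (1 - pt)
    tibble(threshold = pt,
           net_benefit = tp / n - fp / n * w,
           treat_all = prev - (1 - prev) * w,
           treat_none = 0)
  })
  dplyr::bind_rows(rows)
}

#' Exact Shapley attributions for a linear logistic model
#'
#' For a model linear in its features with an independent-feature
#' background, the Shapley value of feature j for patient i on the log-odds
#' scale is `beta_j * (x_ij - mean_j)`, where the mean is taken over the
#' background (training) set. Attributions sum exactly to the patient's
#' log-odds minus the background log-odds.
#'
#' @param model a `linear_logit_fit` (subregion or final model).
#' @param newdata data frame holding the model's features.
#' @param background data frame of background (training) rows used for the
#'   feature means.
#' @return a `shap_report`: list with `values` (patients x features matrix),
#'   `base` (background log-odds), `ranking` (tibble by mean |value|).
#' @export
linear_shap <- function(model, newdata, background) {
  feats <- model$feature_names
  if (!all(feats %in% names(background))) {
    abort("background is missing model features.")
  }
  xb <- as.matrix(background[, feats, drop = FALSE])
  mu <- colMeans(xb)
  x <- as.matrix(newdata[, feats, drop = FALSE])
  beta_std <- model$coefficients
  beta_raw <- beta_std / model$scale
  phi <- sweep(x, 2, mu) * matrix(beta_raw, nrow(x), length(beta_raw),
                                  byrow = TRUE)
  colnames(phi) <- feats
  mus <- (mu - model$center) / model$scale
  base <- model$intercept + sum(beta_std * mus)
  ranking <- tibble(feature = feats,
                    mean_abs_shap = colMeans(abs(phi))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  structure(list(values = phi, base = base, ranking = ranking),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("<shap_report> %d patients x %d features; top: %s\n",
              nrow(x$values), ncol(x$values), x$ranking$feature[1]))
  invisible(x)
}

#' Block-level Shapley aggregates
#'
#' @param report a `shap_report`.
#' @param blocks named list mapping block name to feature names.
#' @return tibble `block`, `mean_abs_shap`.
#' @export
shap_block_summary <- function(report, blocks) {
  rows <- lapply(names(blocks), function(b) {
    cols <- intersect(blocks[[b]], colnames(report$values))
    tot <- if (length(cols)) rowSums(report$values[, cols, drop = FALSE])
    else rep(0, nrow(report$values))
    tibble(block = b, mean_abs_shap = mean(abs(tot)))
  })
  dplyr::bind_rows(rows)
}

#' Cohen's kappa for categorical agreement
#'
#' @param x either a square contingency table/matrix, or a vector of rater-1
#'   calls (then `y` holds rater 2).
#' @param y optional second rater's calls.
#' @return kappa = (po - pe) / (1 - pe); NA with a warning when pe = 1.
#' @export
cohens_kappa <- function(x, y = NULL) {
  tab <- if (is.null(y)) as.matrix(x) else {
    lev <- sort(unique(c(x, y)))
    table(factor(x, lev), factor(y, lev))
  }
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) abort("kappa needs a square table.")
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("degenerate marginals: kappa undefined.")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Two-way random-effects ICC (absolute agreement, single measurement)
#'
#' ICC(2,1): subjects and raters both random, absolute agreement, single
#' measurement, computed from the two-way ANOVA mean squares.
#'
#' @param ratings numeric matrix or data frame, subjects x raters (>= 2
#'   raters).
#' @return the ICC estimate.
#' @export
icc_two_way <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) abort("ICC needs at least 2 raters.")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Grade-comparison tests for a covariate table
#'
#' Applies the conventional test per variable type: Mann-Whitney U for
#' numeric variables, Pearson chi-square for categorical variables with all
#' expected counts >= 5, and Fisher's exact test otherwise. Constant
#' variables are skipped with a note.
#'
#' @param records data frame of covariates.
#' @param group binary grouping vector aligned with rows.
#' @return tibble `variable`, `test`, `p_value`, `note`.
#' @export
cohort_comparison_tests <- function(records, group) {
  vars <- setdiff(names(records), c("patient_id", "grade", "cohort"))
  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    if (length(unique(x)) < 2L) {
      return(tibble(variable = v, test = NA_character_, p_value = NA_real_,
                    note = "constant variable; skipped"))
    }
    n_unique <- length(unique(x))
    if (is.numeric(x) && n_unique > 4L) {
      p <- suppressWarnings(wilcox.test(x ~ group)$p.value)
      return(tibble(variable = v, test = "mann-whitney", p_value = p,
                    note = NA_character_))
    }
    tab <- table(x, group)
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 5)) {
      p <- fisher.test(tab)$p.value
      tibble(variable = v, test = "fisher", p_value = p, note = NA_character_)
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      tibble(variable = v, test = "pearson-chisq", p_value = p,
             note = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Full evaluation report for one model on one cohort
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param threshold decision threshold (training Youden).
#' @param n_bins calibration bins.
#' @return an `eval_report`: list with `auc`, `ci95`, threshold metrics,
#'   `roc` points, `calibration`, `decision` tibbles.
#' @export
eval_report <- function(scores, labels, threshold, n_bins = 10) {
  a <- roc_auc_delong(scores, labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- dplyr::bind_rows(lapply(cuts, function(t) {
    calls <- scores >= t
    tibble(threshold = t,
           tpr = sum(calls & labels == 1L) / sum(labels == 1L),
           fpr = sum(calls & labels == 0L) / sum(labels == 0L))
  }))
  in01 <- all(scores >= 0 & scores <= 1)
  structure(
    list(auc = a$auc, ci95 = a$ci95,
         metrics = threshold_metrics(scores, labels, threshold),
         threshold = threshold, roc = roc,
         calibration = if (in01) calibration_curve(scores, labels, n_bins)
         else NULL,
         decision = if (in01) decision_curve(scores, labels) else NULL),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$ci95[1], x$ci95[2]))
  m <- x$metrics
  cat(sprintf("  sens %.3f  spec %.3f  acc %.3f  prec %s @ threshold %.3f\n",
              m$sensitivity, m$specificity, m$accuracy,
              ifelse(is.na(m$precision), "NA", sprintf("%.3f", m$precision)),
              x$threshold))
  invisible(x)
}
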