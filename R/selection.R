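#' Stratified train/validation split
#'
#' Randomly allocates patients to training and internal-validation cohorts
#' in a fixed ratio using stratified sampling on the binary grade label, so
#' grade proportions are preserved to within one patient per stratum.
#'
#' @param records data frame with at least `patient_id` and `grade` (0/1).
#' @param prop training fraction (default 0.8, the 8:2 split).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return tibble `patient_id`, `grade`, `cohort` ("training" or
#'   "validation").
#' @export
split_cohort <- function(records, prop = 0.8, seed = 1) {
  if (!all(c("patient_id", "grade") %in% names(records))) {
    abort("`records` needs `patient_id` and `grade` columns.")
  }
  set.seed(seed)
  out <- records[, c("patient_id", "grade")]
  out$cohort <- "training"
  for (g in unique(records$grade)) {
    idx <- which(records$grade == g)
    if (length(idx) < 5L) {
      warn(sprintf("grade stratum %s has fewer than 5 patients.", g))
    }
    n_train <- round(length(idx) * prop)
    train_idx <- sample(idx, n_train)
    out$cohort[setdiff(idx, train_idx)] <- "validation"
  }
  as_tibble(out)
}

#' Chi-square filter on median-split features
#'
#' Dichotomizes each continuous feature at its training median and tests the
#' resulting 2x2 table against the binary grade with an uncorrected
#' chi-square test, keeping features with p below `alpha`. Zero-variance
#' features (or degenerate splits) are excluded with a warning.
#'
#' @param features data frame of numeric feature columns (training rows
#'   only).
#' @param labels binary vector (0/1), same length as rows of `features`.
#' @param alpha significance level (default 0.05).
#' @return tibble `feature`, `statistic`, `p_value`, `passed`.
#' @export
chi_square_filter <- function(features, labels, alpha = 0.05) {
  stopifnot(nrow(features) == length(labels))
  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    if (!is.numeric(x) || anyNA(x) || length(unique(x)) < 2L) {
      return(tibble(feature = nm, statistic = NA_real_, p_value = NA_real_,
                    passed = FALSE))
    }
    hi <- x > median(x)
    if (length(unique(hi)) < 2L) {
      return(tibble(feature = nm, statistic = NA_real_, p_value = NA_real_,
                    passed = FALSE))
    }
    tab <- table(factor(hi, c(FALSE, TRUE)), factor(labels, c(0, 1)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(feature = nm, statistic = unname(ct$statistic),
           p_value = unname(ct$p.value),
           passed = is.finite(ct$p.value) && ct$p.value < alpha)
  })
  out <- dplyr::bind_rows(res)
  if (any(is.na(out$statistic))) {
    warn("zero-variance or non-numeric features were excluded from the chi-square filter.")
  }
  out
}

#' LASSO feature selection by cross-validated deviance
#'
#' Standardizes the (training) features, fits an L1-penalized logistic
#' path, chooses the penalty minimizing cross-validated binomial deviance,
#' and returns the nonzero-coefficient features. Deterministic given the
#' seed (fold assignment is drawn from it). Under complete separation the
#' cross-validation can fail; the fallback takes the largest penalty on the
#' path with at most 20 nonzero terms, with a warning.
#'
#' @param features data frame of numeric columns (training rows only).
#' @param labels binary vector (0/1).
#' @param n_folds cross-validation folds (default 10, capped at n).
#' @param seed integer seed.
#' @return list with `selected` (character), `lambda`, `fit` (the glmnet
#'   path), `center`, `scale`.
#' @export
lasso_select <- function(features, labels, n_folds = 10, seed = 1) {
  x <- as.matrix(features)
  keep <- apply(x, 2, function(col) sd(col) > 1e-12)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) {
    return(list(selected = character(0), lambda = NA_real_, fit = NULL,
                center = numeric(0), scale = numeric(0)))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  xs <- scale(x, center = ctr, scale = scl)
  if (ncol(xs) == 1L) {
    ## glmnet needs >= 2 columns; decide by a plain logistic fit
    p <- summary(glm(labels ~ xs[, 1], family = binomial()))$coefficients
    sel <- if (nrow(p) > 1 && p[2, 4] < 0.05) colnames(x) else character(0)
    return(list(selected = sel, lambda = NA_real_, fit = NULL,
                center = ctr, scale = scl))
  }
  set.seed(seed)
  nf <- max(3L, min(n_folds, length(labels)))
  foldid <- sample(rep(seq_len(nf), length.out = length(labels)))
  cvfit <- tryCatch(
    glmnet::cv.glmnet(xs, labels, family = "binomial", foldid = foldid,
                      type.measure = "deviance", standardize = FALSE),
    error = function(e) NULL
  )
  if (is.null(cvfit)) {
    warn("cross-validation failed; falling back to the largest penalty with <= 20 nonzero terms.")
    path <- glmnet::glmnet(xs, labels, family = "binomial",
                           standardize = FALSE)
    nz <- path$df
    lam <- path$lambda[which(nz <= 20)[1]]
    co <- as.matrix(coef(path, s = lam))[-1, 1]
    return(list(selected = names(co)[co != 0], lambda = lam, fit = path,
                center = ctr, scale = scl))
  }
  co <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]
  list(selected = names(co)[co != 0], lambda = cvfit$lambda.min, fit = cvfit,
       center = ctr, scale = scl)
}

## Logistic fit on standardized columns. lambda = 0 gives maximum
## likelihood with a ridge-stabilized fallback under separation; lambda > 0
## fits an L2-penalized model directly (the convention of the common
## reference implementations of multivariable risk models). The internal
## workhorse behind the subregion and final models.
fit_logistic <- function(x, y, lambda = 0, ridge = 1e-4) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, function(col) { s <- sd(col); if (s < 1e-12) 1 else s })
  xs <- scale(x, center = ctr, scale = scl)
  ridge_fit <- function(lam) {
    if (ncol(xs) >= 2L) {
      g <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
      as.numeric(coef(g))
    } else {
      g <- glmnet::glmnet(cbind(xs, 0), y, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
      as.numeric(coef(g))[1:2]
    }
  }
  if (lambda > 0) {
    beta <- ridge_fit(lambda)
  } else {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm.fit(cbind(1, xs), y, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (sep || !fit$converged) {
      warn("separation detected; using a ridge-stabilized logistic fit.")
      beta <- ridge_fit(ridge)
    } else {
      beta <- fit$coefficients
    }
  }
  beta[is.na(beta)] <- 0  # collinear columns contribute nothing
  structure(list(intercept = beta[1], coefficients = beta[-1],
                 feature_names = colnames(x), center = ctr, scale = scl),
            class = "linear_logit_fit")
}

#' @export
predict.linear_logit_fit <- function(object, newdata,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  eta <- object$intercept + as.numeric(xs %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.linear_logit_fit <- function(x, ...) {
  cat(sprintf("<linear_logit_fit> %d features, intercept %.3f\n",
              length(x$coefficients), x$intercept))
  invisible(x)
}

#' Fit a per-subregion grading model
#'
#' Maximum-likelihood logistic regression of grade on the selected
#' (standardized) subregion features, with a ridge-stabilized fallback under
#' separation.
#'
#' @param features data frame holding at least the selected columns
#'   (training rows).
#' @param labels binary grade (0/1).
#' @param selected character vector of selected feature names (>= 1).
#' @param region subregion name carried for provenance.
#' @return a `subregion_model` (the logistic fit plus region tag); predicted
#'   probabilities via `predict()` are always inside (0,1).
#' @export
fit_subregion_model <- function(features, labels, selected,
                                region = NA_character_) {
  if (length(selected) < 1L) abort("at least one selected feature required.")
  fit <- fit_logistic(features[, selected, drop = FALSE], labels)
  fit$region <- region
  class(fit) <- c("subregion_model", class(fit))
  fit
}

#' Patient-level intratumoral heterogeneity index
#'
#' Aggregates the subregion models' output probabilities into a scalar ITH
#' index: the unweighted mean of the probabilities of the chosen subregion
#' subset. A singleton subset returns that probability unchanged. Missing
#' probabilities (empty habitats) are dropped from the mean and flagged.
#'
#' @param probabilities named numeric vector (or one-row data frame) of
#'   per-subregion probabilities in (0,1).
#' @param subset character vector of subregion names to aggregate.
#' @return scalar in `[0, 1]`; attribute `incomplete` is TRUE when members
#'   were missing.
#' @export
ith_index <- function(probabilities, subset) {
  probabilities <- unlist(probabilities)
  if (!all(subset %in% names(probabilities))) {
    abort("subset contains subregions without probabilities.")
  }
  vals <- probabilities[subset]
  incomplete <- anyNA(vals)
  if (all(is.na(vals))) abort("no subregion probability available.")
  out <- mean(vals, na.rm = TRUE)
  attr(out, "incomplete") <- incomplete
  out
}

#' Enumerate the candidate habitat-model subsets
#'
#' All four singleton subregions plus every subset containing at least one
#' subregion from each sequence: the four cross-sequence pairs, the four
#' triples and the full quadruple -- 13 candidates in total. The two
#' within-sequence pairs are excluded.
#'
#' @return list of character vectors (subregion name subsets), length 13.
#' @export
enumerate_candidates <- function() {
  regions <- c("T2WI_habitat1", "T2WI_habitat2", "DWI_habitat1",
               "DWI_habitat2")
  is_t2 <- grepl("^T2WI", regions)
  out <- list()
  for (size in 1:4) {
    combos <- utils::combn(regions, size, simplify = FALSE)
    for (cb in combos) {
      t2n <- sum(cb %in% regions[is_t2])
      dwn <- length(cb) - t2n
      if (size == 1L || (t2n >= 1L && dwn >= 1L)) {
        out[[length(out) + 1L]] <- cb
      }
    }
  }
  out
}

#' Select the final habitat model on internal-validation AUC
#'
#' Scores every candidate subset by the AUC of its ITH index on the
#' internal-validation cohort and picks the argmax (ties: smaller subset,
#' then lexicographic). The winning index is wrapped with a logistic
#' recalibration fitted on the training cohort only.
#'
#' @param subregion_probs data frame of per-subregion probabilities, one
#'   row per patient, columns named by subregion.
#' @param labels binary grade aligned with rows.
#' @param is_training logical vector; TRUE rows fit the calibration, FALSE
#'   rows drive the selection.
#' @param candidates list of subsets (default [enumerate_candidates()]).
#' @return a `habitat_model`: `subset`, `candidates` (tibble with validation
#'   AUC per candidate), `calibration` (a `linear_logit_fit`).
#' @export
select_habitat_model <- function(subregion_probs, labels, is_training,
                                 candidates = enumerate_candidates()) {
  idx_of <- function(subset) {
    apply(subregion_probs[, subset, drop = FALSE], 1, mean, na.rm = TRUE)
  }
  val <- !is_training
  scores <- vapply(candidates, function(cb) {
    roc_auc_delong(idx_of(cb)[val], labels[val])$auc
  }, numeric(1))
  key <- vapply(candidates, function(cb) paste(sort(cb), collapse = "+"),
                character(1))
  sizes <- lengths(candidates)
  ord <- order(-scores, sizes, key)
  best <- candidates[[ord[1]]]
  ith_train <- idx_of(best)[is_training]
  calibration <- fit_logistic(data.frame(ith_index = ith_train),
                              labels[is_training])
  structure(
    list(subset = best,
         candidates = tibble(subset = key, size = sizes,
                             validation_auc = scores),
         calibration = calibration),
    class = "habitat_model"
  )
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> subset: %s (13 candidates scored)\n",
              paste(x$subset, collapse = " + ")))
  invisible(x)
}

#' ITH index of a fitted habitat model
#' @param model a `habitat_model`.
#' @param subregion_probs data frame of per-subregion probabilities.
#' @param calibrated logical; return the recalibrated probability instead of
#'   the raw index.
#' @return numeric vector.
#' @export
habitat_index <- function(model, subregion_probs, calibrated = FALSE) {
  idx <- apply(subregion_probs[, model$subset, drop = FALSE], 1, mean,
               na.rm = TRUE)
  if (!calibrated) return(idx)
  predict(model$calibration, data.frame(ith_index = idx))
}

#' Univariable and multivariable logistic screening of covariates
#'
#' Each covariate is tested in a univariable logistic regression of grade;
#' covariates significant at `alpha` enter a joint multivariable fit, and
#' the retained set is those still significant there (Wald tests).
#'
#' @param records data frame with a binary `grade` column and covariates
#'   (binary 0/1 or numeric); `patient_id`/`cohort` columns are ignored.
#' @param alpha significance level.
#' @return list with `table` (tibble: variable, odds ratio, CI, p for both
#'   stages) and `retained` (character).
#' @export
univariable_multivariable_lr <- function(records, alpha = 0.05) {
  vars <- setdiff(names(records), c("patient_id", "grade", "cohort"))
  y <- records$grade
  uni <- lapply(vars, function(v) {
    x <- records[[v]]
    if (length(unique(x)) < 2L) {
      warn(sprintf("covariate %s is constant; dropped.", v))
      return(tibble(variable = v, or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_))
    }
    s <- summary(glm(y ~ x, family = binomial()))$coefficients
    est <- s[2, 1]; se <- s[2, 2]
    tibble(variable = v, or = exp(est), ci_low = exp(est - 1.96 * se),
           ci_high = exp(est + 1.96 * se), p_value = s[2, 4])
  })
  tab <- dplyr::bind_rows(uni)
  sig <- tab$variable[!is.na(tab$p_value) & tab$p_value < alpha]
  tab$multi_or <- NA_real_
  tab$multi_p <- NA_real_
  retained <- character(0)
  if (length(sig) > 0) {
    mdata <- records[, c("grade", sig), drop = FALSE]
    mfit <- glm(grade ~ ., data = mdata, family = binomial())
    ms <- summary(mfit)$coefficients
    for (v in sig) {
      row <- grep(paste0("^", v), rownames(ms))[1]
      if (!is.na(row)) {
        tab$multi_or[tab$variable == v] <- exp(ms[row, 1])
        tab$multi_p[tab$variable == v] <- ms[row, 4]
        if (ms[row, 4] < alpha) retained <- c(retained, v)
      }
    }
  }
  list(table = tab, retained = retained)
}

#' Fit the seven final grading models
#'
#' Logistic models on the seven block unions of the design: the three base
#' blocks (clinical/laboratory/imaging covariates, whole-tumor radiomics,
#' habitat ITH index), their three pairwise fusions, and the full
#' combination. Each model stores a training-set Youden threshold. An empty
#' block skips the models that need it, surfaced in the bundle.
#'
#' @param blocks named list of data frames (`clinlabimag`, `radiomics`,
#'   `habitat`) with aligned training rows.
#' @param labels binary grade for the training rows.
#' @param lambda L2 penalty of the final fits; the default `1/n` matches the
#'   weak default regularization of common logistic-regression toolkits and
#'   keeps high-dimensional fused blocks stable.
#' @return a `model_bundle`: named list of `linear_logit_fit`s keyed
#'   ClinLabImag, Radiomics, Habitat, ClinLabImag-Radiomics,
#'   ClinLabImag-Habitat, Radiomics-Habitat, Combined, plus `thresholds`
#'   and `skipped`.
#' @export
fit_final_models <- function(blocks, labels, lambda = 1 / length(labels)) {
  stopifnot(all(c("clinlabimag", "radiomics", "habitat") %in% names(blocks)))
  spec <- list(
    ClinLabImag = "clinlabimag",
    Radiomics = "radiomics",
    Habitat = "habitat",
    `ClinLabImag-Radiomics` = c("clinlabimag", "radiomics"),
    `ClinLabImag-Habitat` = c("clinlabimag", "habitat"),
    `Radiomics-Habitat` = c("radiomics", "habitat"),
    Combined = c("clinlabimag", "radiomics", "habitat")
  )
  models <- list(); thresholds <- c(); skipped <- character(0)
  for (nm in names(spec)) {
    parts <- spec[[nm]]
    empty <- vapply(parts, function(b) is.null(blocks[[b]]) ||
                      ncol(blocks[[b]]) == 0L, logical(1))
    if (any(empty)) {
      skipped <- c(skipped, nm)
      next
    }
    X <- dplyr::bind_cols(blocks[parts])
    fit <- fit_logistic(X, labels, lambda = lambda)
    p <- predict(fit, X)
    models[[nm]] <- fit
    thresholds[nm] <- youden_threshold(p, labels)
  }
  if (length(skipped)) {
    warn(paste("models skipped due to empty blocks:",
               paste(skipped, collapse = ", ")))
  }
  structure(list(models = models, thresholds = thresholds,
                 block_names = lapply(blocks, names), skipped = skipped),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d fitted models: %s\n", length(x$models),
              paste(names(x$models), collapse = ", ")))
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted probabilities of every model in a bundle
#'
#' @param bundle a `model_bundle`.
#' @param blocks named list of data frames with the same columns used at
#'   fit time (any rows).
#' @return tibble with one probability column per model.
#' @export
predict_bundle <- function(bundle, blocks) {
  X <- dplyr::bind_cols(blocks)
  out <- lapply(bundle$models, function(m) predict(m, X))
  as_tibble(out)
}
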