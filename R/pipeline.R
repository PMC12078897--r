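#' Pipeline configuration
#'
#' Bundles every stage's settings and seeds so a run is fully determined by
#' one object: the synthetic-cohort config, the feature-extraction config,
#' whether artifacts and preprocessing run, how K is chosen, and the
#' split/selection seeds. Round-trips losslessly through JSON (the cohort
#' and feature configs are plain lists).
#'
#' @param cohort a [cohort_config()].
#' @param features a [feature_config()]; the default extracts the original
#'   image type only, which keeps desk-scale runs fast (the full 21-type
#'   bank is available via `feature_config("all")`).
#' @param artifacts logical; apply acquisition artifacts and run the
#'   preprocessing chain (bias correction, training-learned histogram
#'   standardization, DWI registration).
#' @param k habitats per sequence, or `"elbow"` to select K by the pooled
#'   cohort SSE elbow.
#' @param kmax elbow scan upper bound.
#' @param split_prop,split_seed stratified split settings.
#' @param selection_seed seed for LASSO fold assignment.
#' @param alpha significance level for the chi-square and covariate screens.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(n_patients = 60),
                            features = feature_config("original"),
                            artifacts = FALSE,
                            k = "elbow", kmax = 8,
                            split_prop = 0.8, split_seed = 11,
                            selection_seed = 13, alpha = 0.05) {
  structure(list(cohort = cohort, features = features, artifacts = artifacts,
                 k = k, kmax = kmax, split_prop = split_prop,
                 split_seed = split_seed, selection_seed = selection_seed,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Train the subregion, habitat and seven final grading models
#'
#' Implements the modelling design end to end with strict train/validation
#' separation: per-subregion chi-square filter (training medians), LASSO
#' selection, logistic subregion models, candidate enumeration and
#' internal-validation selection of the habitat model, whole-tumor radiomics
#' selection, univariable/multivariable covariate screening, and the seven
#' final logistic models with training Youden thresholds. No validation row
#' influences any selection, standardization constant, threshold or
#' calibration.
#'
#' @param features tibble from [extract_cohort_features()] (`patient_id`,
#'   `grade`, feature columns named `region|image_type|class|feature`).
#' @param covariates tibble from [cohort_covariates()].
#' @param split tibble from [split_cohort()].
#' @param seed seed for LASSO fold assignment.
#' @param alpha significance level of the screens.
#' @return an `ith_workflow` list: `subregion` (per-region selection and
#'   model), `subregion_probs`, `habitat_model`, `radiomics_selected`,
#'   `clinlab`, `blocks` (model matrices for all rows), `bundle`, `split`.
#' @export
train_grading_models <- function(features, covariates, split, seed = 13,
                                 alpha = 0.05) {
  stopifnot(identical(features$patient_id, split$patient_id),
            identical(covariates$patient_id, split$patient_id))
  is_train <- split$cohort == "training"
  y <- features$grade
  y_train <- y[is_train]

  subregions <- c("T2WI_habitat1", "T2WI_habitat2", "DWI_habitat1",
                  "DWI_habitat2")
  subregion <- list()
  probs <- list()
  for (i in seq_along(subregions)) {
    rg <- subregions[i]
    cols <- grep(paste0("^", rg, "\\|"), names(features), value = TRUE)
    block <- features[, cols, drop = FALSE]
    block <- block[, vapply(block, function(cc) !anyNA(cc), logical(1)),
                   drop = FALSE]
    chi <- chi_square_filter(block[is_train, , drop = FALSE], y_train, alpha)
    passed <- chi$feature[chi$passed]
    sel <- if (length(passed) >= 1L) {
      lasso_select(block[is_train, passed, drop = FALSE], y_train,
                   seed = seed + i)
    } else list(selected = character(0))
    chosen <- sel$selected
    if (length(chosen) == 0L) {
      ## degenerate selection: keep the strongest chi-square feature so the
      ## subregion model exists
      warn(sprintf("no feature survived selection for %s; using the top chi-square feature.", rg))
      chosen <- chi$feature[order(chi$p_value)][1]
    }
    fit <- fit_subregion_model(block[is_train, , drop = FALSE], y_train,
                               chosen, region = rg)
    subregion[[rg]] <- list(chi = chi, selected = chosen, model = fit)
    probs[[rg]] <- predict(fit, block)
  }
  subregion_probs <- as_tibble(probs)

  habitat_model <- select_habitat_model(subregion_probs, y, is_train)
  ith_all <- habitat_index(habitat_model, subregion_probs)

  whole_cols <- grep("^whole_", names(features), value = TRUE)
  wblock <- features[, whole_cols, drop = FALSE]
  wblock <- wblock[, vapply(wblock, function(cc) !anyNA(cc), logical(1)),
                   drop = FALSE]
  chi_w <- chi_square_filter(wblock[is_train, , drop = FALSE], y_train, alpha)
  passed_w <- chi_w$feature[chi_w$passed]
  sel_w <- if (length(passed_w)) {
    lasso_select(wblock[is_train, passed_w, drop = FALSE], y_train,
                 seed = seed + 9)
  } else list(selected = character(0))
  rad_selected <- sel_w$selected
  if (length(rad_selected) == 0L) {
    warn("no whole-tumor feature survived selection; using the top chi-square feature.")
    rad_selected <- chi_w$feature[order(chi_w$p_value)][1]
  }

  cov_cols <- setdiff(names(covariates), c("patient_id", "grade"))
  clinlab <- univariable_multivariable_lr(
    covariates[is_train, c("grade", cov_cols)], alpha = alpha
  )

  blocks_all <- list(
    clinlabimag = covariates[, clinlab$retained, drop = FALSE],
    radiomics = wblock[, rad_selected, drop = FALSE],
    habitat = tibble(ith_index = ith_all)
  )
  blocks_train <- lapply(blocks_all, function(b) b[is_train, , drop = FALSE])
  bundle <- fit_final_models(blocks_train, y_train)

  structure(
    list(subregion = subregion, subregion_probs = subregion_probs,
         habitat_model = habitat_model, radiomics_selected = rad_selected,
         clinlab = clinlab, blocks = blocks_all, bundle = bundle,
         split = split, grade = y),
    class = "ith_workflow"
  )
}

#' @export
print.ith_workflow <- function(x, ...) {
  cat("<ith_workflow>\n")
  cat("  habitat subset:", paste(x$habitat_model$subset, collapse = " + "),
      "\n")
  cat("  radiomics features:", length(x$radiomics_selected), "\n")
  cat("  covariates retained:", paste(x$clinlab$retained, collapse = ", "),
      "\n")
  cat("  fitted final models:", length(x$bundle$models), "\n")
  invisible(x)
}

#' Evaluate every fitted model of a workflow on both cohorts
#'
#' @param workflow an `ith_workflow`.
#' @return tibble with one row per model and cohort: AUC, DeLong 95% CI and
#'   the four threshold metrics at the training Youden threshold.
#' @export
evaluate_workflow <- function(workflow) {
  is_train <- workflow$split$cohort == "training"
  preds <- predict_bundle(workflow$bundle, workflow$blocks)
  rows <- list()
  for (nm in names(preds)) {
    for (ch in c("training", "validation")) {
      sel <- if (ch == "training") is_train else !is_train
      rep <- eval_report(preds[[nm]][sel], workflow$grade[sel],
                         workflow$bundle$thresholds[[nm]])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(model = nm, cohort = ch, auc = rep$auc,
               ci_low = rep$ci95[1], ci_high = rep$ci95[2]),
        rep$metrics
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Pairwise DeLong comparisons between fitted models
#'
#' @param workflow an `ith_workflow`.
#' @param cohort `"training"` or `"validation"`.
#' @return tibble `model_a`, `model_b`, `auc_a`, `auc_b`, `p_value`.
#' @export
delong_comparisons <- function(workflow, cohort = "validation") {
  sel <- if (cohort == "training") workflow$split$cohort == "training"
  else workflow$split$cohort != "training"
  preds <- predict_bundle(workflow$bundle, workflow$blocks)
  nms <- names(preds)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    dt <- delong_test(preds[[nms[i]]][sel], preds[[nms[j]]][sel],
                      workflow$grade[sel])
    rows[[length(rows) + 1L]] <- tibble(
      model_a = nms[i], model_b = nms[j], auc_a = dt$auc_a, auc_b = dt$auc_b,
      p_value = dt$p_value
    )
  }
  dplyr::bind_rows(rows)
}

#' Run the full habitat-ITH pipeline
#'
#' Executes simulate (+ optional artifacts and preprocessing), habitat
#' clustering with elbow or fixed K, feature extraction, model training and
#' evaluation, and writes features, model summaries, evaluation reports and
#' a manifest into `out_dir`. Rerunning with the same config reproduces all
#' numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return a `pipeline_run` list: `cohort_k`, `features`, `workflow`,
#'   `evaluation`, `delong`, `shap`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cohort <- generate_cohort(config$cohort)
  split <- split_cohort(cohort_covariates(cohort), prop = config$split_prop,
                        seed = config$split_seed)

  if (isTRUE(config$artifacts)) {
    cohort_art <- lapply(cohort, apply_artifacts, config = config$cohort)
    is_train <- split$cohort == "training"
    train_t2 <- lapply(cohort_art[is_train], function(p) p$t2w)
    train_dwi <- lapply(cohort_art[is_train], function(p) p$dwi)
    landmarks <- list(T2WI = learn_landmarks(train_t2),
                      DWI = learn_landmarks(train_dwi))
    cohort <- structure(
      lapply(cohort_art, preprocess_patient, landmarks = landmarks,
             spacing = NULL, register = TRUE, deformable = TRUE),
      class = "mri_cohort", config = config$cohort
    )
  }

  if (identical(config$k, "elbow")) {
    elbow <- cohort_elbow(cohort, kmax = config$kmax,
                          seed = config$cohort$seed)
    k <- elbow$k
  } else {
    elbow <- NULL
    k <- as.integer(config$k)
  }

  features <- extract_cohort_features(cohort, k = k,
                                      config = config$features,
                                      seed = config$cohort$seed)
  covariates <- cohort_covariates(cohort)
  workflow <- train_grading_models(features, covariates, split,
                                   seed = config$selection_seed,
                                   alpha = config$alpha)
  evaluation <- evaluate_workflow(workflow)
  delong <- delong_comparisons(workflow, cohort = "validation")
  shap <- if ("Combined" %in% names(workflow$bundle$models)) {
    is_train <- split$cohort == "training"
    X_all <- dplyr::bind_cols(workflow$blocks)
    linear_shap(workflow$bundle$models$Combined, X_all,
                X_all[is_train, , drop = FALSE])
  } else NULL

  run <- structure(
    list(cohort_k = k, elbow = elbow, features = features,
         workflow = workflow, evaluation = evaluation, delong = delong,
         shap = shap, config = config),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d patients, K = %d\n",
              nrow(x$features), x$cohort_k))
  print(x$evaluation, n = 14)
  invisible(x)
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(run$features, file.path(out_dir, "features.csv"))
  write_table(run$evaluation, file.path(out_dir, "evaluation.csv"))
  write_table(run$delong, file.path(out_dir, "delong_tests.csv"))
  write_table(run$workflow$habitat_model$candidates,
              file.path(out_dir, "habitat_candidates.csv"))
  coefs <- dplyr::bind_rows(lapply(names(run$workflow$bundle$models),
    function(nm) {
      m <- run$workflow$bundle$models[[nm]]
      tibble(model = nm, term = c("(Intercept)", m$feature_names),
             estimate = c(m$intercept, m$coefficients))
    }))
  write_table(coefs, file.path(out_dir, "model_coefficients.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("habitomics")),
    n_patients = run$config$cohort$n_patients,
    seed = run$config$cohort$seed,
    k = run$cohort_k,
    image_types = run$config$features$image_types,
    config_hash = rlang::hash(unclass(run$config)),
    files = c("features.csv", "evaluation.csv", "delong_tests.csv",
              "habitat_candidates.csv", "model_coefficients.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
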