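#' Tidy a fitted logistic model
#'
#' @param x a `linear_logit_fit` (subregion or final model).
#' @param ... unused.
#' @return tibble with `term` and `estimate` (log-odds on the standardized
#'   feature scale; the intercept is on the probability-link scale).
#' @export
tidy.linear_logit_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$feature_names),
         estimate = c(x$intercept, x$coefficients))
}

#' @rdname tidy.linear_logit_fit
#' @export
glance.linear_logit_fit <- function(x, ...) {
  tibble(n_features = length(x$coefficients))
}

#' Tidy a habitat model
#'
#' @param x a `habitat_model`.
#' @param ... unused.
#' @return the candidate table with the winning subset flagged.
#' @export
tidy.habitat_model <- function(x, ...) {
  out <- x$candidates
  out$selected <- out$subset == paste(sort(x$subset), collapse = "+")
  out
}

#' @rdname tidy.habitat_model
#' @export
glance.habitat_model <- function(x, ...) {
  tibble(subset = paste(x$subset, collapse = "+"),
         n_candidates = nrow(x$candidates),
         best_validation_auc = max(x$candidates$validation_auc))
}

#' Tidy a model bundle
#'
#' @param x a `model_bundle`.
#' @param ... unused.
#' @return coefficients of every fitted model, long format.
#' @export
tidy.model_bundle <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(nm) {
    dplyr::bind_cols(tibble(model = nm), tidy(x$models[[nm]]))
  }))
}

#' @rdname tidy.model_bundle
#' @export
glance.model_bundle <- function(x, ...) {
  tibble(model = names(x$models),
         n_features = vapply(x$models, function(m)
           length(m$coefficients), integer(1)),
         threshold = unname(x$thresholds[names(x$models)]))
}

#' Tidy an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return one-row tibble with AUC, CI and threshold metrics.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(auc = x$auc, ci_low = x$ci95[1], ci_high = x$ci95[2],
           threshold = x$threshold),
    x$metrics
  )
}
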