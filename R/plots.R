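#' Plot an SSE elbow curve
#'
#' @param object a tibble with `k` and `sse` columns (e.g. [sse_curve()] or
#'   the `mean_curve` of [cohort_elbow()]).
#' @param selected_k optional K to highlight.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sse_curve <- function(object, selected_k = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K",
                  y = "within-cluster SSE") +
    ggplot2::theme_minimal()
  if (!is.null(selected_k)) {
    p <- p + ggplot2::geom_vline(xintercept = selected_k, linetype = 2)
  }
  p
}

#' ROC curves of every model in a workflow evaluation
#'
#' @param workflow an `ith_workflow`.
#' @param cohort `"training"` or `"validation"`.
#' @return a ggplot of the ROC point sets.
#' @export
plot_roc <- function(workflow, cohort = "validation") {
  sel <- if (cohort == "training") workflow$split$cohort == "training"
  else workflow$split$cohort != "training"
  preds <- predict_bundle(workflow$bundle, workflow$blocks)
  dat <- dplyr::bind_rows(lapply(names(preds), function(nm) {
    rep <- eval_report(preds[[nm]][sel], workflow$grade[sel],
                       workflow$bundle$thresholds[[nm]])
    dplyr::bind_cols(tibble(model = nm), rep$roc)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    color = .data$model)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = paste("ROC,", cohort, "cohort")) +
    ggplot2::theme_minimal()
}

#' Calibration plot for one model
#'
#' @param curve output of [calibration_curve()].
#' @return a ggplot of observed vs predicted risk per bin.
#' @export
plot_calibration <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$mean_predicted,
                                      y = .data$observed)) +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability",
                  y = "observed event rate") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot for one model
#'
#' @param curve output of [decision_curve()].
#' @return a ggplot of net benefit against threshold probability.
#' @export
plot_decision_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("net_benefit", "treat_all",
                                       "treat_none"),
                              names_to = "strategy", values_to = "nb")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                     color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit") +
    ggplot2::theme_minimal()
}

#' Heatmap of Shapley attributions
#'
#' @param report a `shap_report`.
#' @param max_features show at most this many top-ranked features.
#' @return a ggplot heatmap (patients x features).
#' @export
plot_shap <- function(report, max_features = 20) {
  feats <- head(report$ranking$feature, max_features)
  dat <- as_tibble(report$values[, feats, drop = FALSE])
  dat$patient <- seq_len(nrow(dat))
  long <- tidyr::pivot_longer(dat, -"patient", names_to = "feature",
                              values_to = "shap")
  long$feature <- factor(long$feature, levels = rev(feats))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$feature,
                                     fill = .data$shap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "patient", y = NULL, fill = "SHAP\n(log-odds)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
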