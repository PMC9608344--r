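#' Boxplots of global metrics by clinical profile
#'
#' @param metrics Long metric table from [compute_metrics()] at one `tau`.
#' @param stars Optional [compare_all_pairs()] result; significant pairs are
#'   listed in the subtitle.
#' @return A ggplot object (one facet per metric, free scales).
#' @export
plot_group_boxplots <- function(metrics, stars = NULL) {
  sub <- NULL
  if (!is.null(stars)) {
    sig <- dplyr::filter(stars, .data$stars != "")
    if (nrow(sig) > 0) {
      sub <- paste("significant:", paste(
        paste0(sig$pair, " [", sig$metric, "] ", sig$stars), collapse = "; "))
    }
  }
  ggplot2::ggplot(dplyr::filter(metrics, !is.na(.data$value)),
                  ggplot2::aes(x = .data$profile, y = .data$value,
                               fill = .data$profile)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = paste0("Global graph metrics by clinical profile (tau = ",
                                 unique(metrics$tau), ")"),
                  subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Coefficient-of-variation sweep plot
#'
#' CV\% of each global metric across the percentile-threshold grid; the
#' usual way to eyeball the informative working range of `tau`.
#'
#' @param object A `gm_cv_table` from [cv_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gm_cv_table <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$cv)),
                  ggplot2::aes(x = .data$tau, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(tau), y = "CV %",
                  title = "Metric variability across percentile thresholds") +
    ggplot2::theme_minimal()
}

#' Per-fold ROC curves of an experiment
#'
#' @param object A `gm_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object with one curve per cross-validation fold.
#' @exportS3Method ggplot2::autoplot
autoplot.gm_experiment <- function(object, ...) {
  roc <- purrr::map2_dfr(object$folds$roc, object$folds$fold,
                         ~ dplyr::mutate(.x, fold = factor(.y)))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$fold)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = paste0("ROC per fold: ", object$config$pair$label),
                  subtitle = sprintf("mean AUC = %.3f",
                                     object$aggregate$auc_mean)) +
    ggplot2::theme_minimal()
}
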