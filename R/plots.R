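#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of a cross-validation result
#'
#' @param object An `nfs_cv`.
#' @param ... Unused.
#' @return A ggplot: out-of-fold ROC curve with the AUC in the subtitle.
#' @export
autoplot.nfs_cv <- function(object, ...) {
  roc <- roc_auc(object$predictions$decision, object$predictions$label)
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%d-fold cross-validated ROC", object$k),
      subtitle = sprintf("AUC = %.3f, MCC = %.3f", roc$auc,
                         object$metrics$mcc)) +
    ggplot2::theme_minimal()
}

#' Feature-selection trace plot
#'
#' @param object An `nfs_trace`.
#' @param ... Unused.
#' @return A ggplot of cross-validated MCC against selection step.
#' @export
autoplot.nfs_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$step, y = .data$mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature), hjust = -0.1,
                       vjust = -0.6, size = 3) +
    ggplot2::scale_x_continuous(breaks = object$trace$step) +
    ggplot2::labs(x = "Features selected", y = "Cross-validated MCC",
                  title = "Greedy forward feature selection") +
    ggplot2::theme_minimal()
}

#' MAF bin plot
#'
#' Mean predicted disease probability against mean minor allele frequency
#' per bin, with the least-squares line.
#'
#' @param object An `nfs_maf_bins`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nfs_maf_bins <- function(object, ...) {
  filled <- object$bins[object$bins$n > 0, ]
  ggplot2::ggplot(filled, ggplot2::aes(x = .data$mean_maf,
                                       y = .data$mean_prob)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "#2166ac",
                        alpha = 0.8) +
    ggplot2::labs(
      x = "Mean minor allele frequency (bin)",
      y = "Mean predicted disease probability",
      title = "Predicted risk against population allele frequency",
      subtitle = sprintf("Pearson r = %.2f over %d non-empty bins",
                         object$r, nrow(filled)),
      size = "Records") +
    ggplot2::theme_minimal()
}

#' Class-conditional feature distribution plot
#'
#' Density plot of one feature split by class label — the standard visual
#' check that disease sites sit at lower disorder/ASA and higher
#' conservation than neutral sites.
#'
#' @param data Feature tibble with a `label` column.
#' @param feature Feature column name (string).
#' @return A ggplot.
#' @export
plot_feature_density <- function(data, feature) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[feature]],
                                     fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::scale_fill_manual(values = c(disease = "#b2182b",
                                          neutral = "#2166ac")) +
    ggplot2::labs(x = feature, y = "Density", fill = NULL) +
    ggplot2::theme_minimal()
}
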