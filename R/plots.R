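# ggplot2 visualizations for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.npp_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npp_cv <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(subtitle = sprintf("%d-fold cross-validation, ACC = %.3f",
                                     max(object$predictions$fold),
                                     object$metrics$ACC))
}

#' @export
autoplot.npp_logodds <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(unclass(object), rownames = "first"),
    -"first", names_to = "second", values_to = "log_odds")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$second, y = .data$first,
                                   fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", mid = "mistyrose",
                                  high = "red3", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev(aa_alphabet())) +
    ggplot2::labs(x = "Second residue", y = "First residue",
                  fill = "log-odds",
                  title = "Dipeptide enrichment (positive vs negative)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npp_relief <- function(object, top_n = 30L, ...) {
  df <- utils::head(object[order(object$rank), ], top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$weight),
                                   y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ReliefF weight",
                  title = paste("Top", nrow(df), "features by ReliefF weight")) +
    ggplot2::theme_minimal()
}
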