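#' ROC and precision-recall curve points
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return `roc_curve()`: a tibble with `threshold`, `fpr`, `tpr`;
#'   `pr_curve()`: a tibble with `threshold`, `recall`, `precision`.
#' @export
roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tibble::tibble(threshold = s[last],
                 fpr = cumsum(y == 0)[last] / nn,
                 tpr = cumsum(y == 1)[last] / np) |>
    (\(d) dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), d))()
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  np <- sum(labels == 1)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  tibble::tibble(threshold = s[last], recall = tp / np,
                 precision = tp / (tp + fp))
}

#' Plot ROC or precision-recall curves
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return A ggplot.
#' @export
plot_roc <- function(scores, labels) {
  d <- roc_curve(scores, labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUROC = %.3f)", auroc(scores, labels))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
plot_pr <- function(scores, labels) {
  d <- pr_curve(scores, labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Precision-recall (AUPR = %.3f)",
                                  aupr(scores, labels))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training trace
#'
#' Loss and the seven validation metrics against the training epoch.
#'
#' @param object A `premir_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.premir_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, -"epoch", names_to = "metric",
                           values_to = "value")
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `premir_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.premir_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$fold_metrics, -"fold",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.1, height = 0,
                         ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = NULL, y = "Score", colour = "Fold") +
    ggplot2::theme_minimal()
}
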