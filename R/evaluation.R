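#' Confusion counts at a decision threshold
#'
#' @param scores Numeric scores/probabilities.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Decision threshold; scores `>= threshold` are called
#'   positive (default 0.5).
#' @return A named list of class `confusion_counts` with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) abort("empty input", class = "premir_format_error")
  if (length(scores) != length(labels)) {
    abort("scores and labels differ in length", class = "premir_format_error")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("labels must be 0 or 1", class = "premir_format_error")
  }
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Threshold classification metrics from confusion counts
#'
#' Computes sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' positive predictive value `PPV = TP/(TP+FP)`, `F = 2TP/(2TP+FP+FN)` and
#' the geometric mean `g = sqrt(SE * SP)`. A metric whose denominator is
#' zero is reported as 0 and flagged in the `undefined` attribute.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return A one-row tibble with columns `se`, `sp`, `ppv`, `f_score`,
#'   `g_mean`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  undefined <- character(0)
  if (counts$TP + counts$FN == 0) undefined <- c(undefined, "se")
  if (counts$TN + counts$FP == 0) undefined <- c(undefined, "sp")
  if (counts$TP + counts$FP == 0) undefined <- c(undefined, "ppv")
  se <- safe_div(counts$TP, counts$TP + counts$FN)
  sp <- safe_div(counts$TN, counts$TN + counts$FP)
  out <- tibble::tibble(
    se = se,
    sp = sp,
    ppv = safe_div(counts$TP, counts$TP + counts$FP),
    f_score = safe_div(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN),
    g_mean = sqrt(se * sp))
  attr(out, "undefined") <- undefined
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midranks for ties; equivalent to
#' trapezoidal integration of the ROC curve over all thresholds.
#'
#' @inheritParams confusion
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("AUROC needs both classes present", class = "premir_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation (precision held constant between successive
#' recall points, i.e. average precision): `sum over thresholds of
#' (R_k - R_{k-1}) * P_k`, sweeping unique score values from high to low.
#'
#' @inheritParams confusion
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("AUPR needs both classes present", class = "premir_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate only at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  recall <- tp[last] / np
  precision <- tp[last] / (tp[last] + fp[last])
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)
}

#' Full metrics report for scored examples
#'
#' Combines the five threshold metrics with AUROC and AUPR.
#'
#' @inheritParams confusion
#' @return A one-row tibble: `se`, `sp`, `ppv`, `f_score`, `g_mean`,
#'   `auroc`, `aupr`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  dplyr::bind_cols(
    classification_metrics(confusion(scores, labels, threshold)),
    tibble::tibble(auroc = auroc(scores, labels),
                   aupr = aupr(scores, labels)))
}

#' Relative improvement over a competitor, in percent
#'
#' `100 * (ours - best_other) / best_other`, rounded to two decimals — the
#' standard way benchmark tables quote how far one method's metric sits
#' above the best competing method's.
#'
#' @param ours Our metric value.
#' @param best_other Best competing value (> 0).
#' @return Percentage, rounded to 2 decimal places.
#' @examples
#' relative_improvement(0.995, 0.903) # 10.19
#' @export
relative_improvement <- function(ours, best_other) {
  if (any(best_other <= 0)) {
    abort("best_other must be positive", class = "premir_metric_error")
  }
  round(100 * (ours - best_other) / best_other, 2)
}

#' Published benchmark metrics for pre-miRNA classifiers
#'
#' Returns the package's bundled table of benchmark results reported in the
#' literature for pre-miRNA identification methods (miRBoost, microPred,
#' deepMiRGene, fixed- and variable-sized deep CNNs, and the cascaded
#' CNN-BLSTM this package implements) on the human, cross-species and new
#' hairpin datasets, together with per-dataset class counts. Used by the
#' comparative-arithmetic helpers and the acceptance checks.
#'
#' @param which `"metrics"` for the per-method metric table, `"counts"`
#'   for the per-dataset positive/negative counts.
#' @return A tibble.
#' @export
benchmark_table <- function(which = c("metrics", "counts")) {
  which <- match.arg(which)
  file <- if (which == "metrics") "benchmark_metrics.tsv" else "dataset_counts.tsv"
  path <- system.file("extdata", file, package = "premirnet")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "-")
}
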