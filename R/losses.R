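#' Loss configuration
#'
#' Configures the training loss: focal loss (the default), class-weighted
#' cross-entropy, or plain cross-entropy.
#'
#' The focal loss follows the original convention: with `p_y` the predicted
#' probability of the true class, the per-example loss is
#' `(1 - p_y)^gamma * (-alpha_y * log(p_y))`, where `alpha_y = alpha` for
#' the positive class and `1 - alpha` for the negative class. Note that the
#' default `alpha = 0.25` weights the positive (minority) class *down*;
#' the focusing term `(1 - p_y)^gamma` is what rebalances training towards
#' hard examples, and with abundant easy negatives the net effect favours
#' the minority class.
#'
#' @param kind `"focal"`, `"weighted_ce"` or `"ce"`.
#' @param gamma Focusing parameter, >= 0 (default 2).
#' @param alpha Positive-class weighting factor in \[0, 1\] (default 0.25).
#' @param class_weights Length-2 nonnegative vector `(w_pos, w_neg)` for
#'   `kind = "weighted_ce"` (default `c(0.9, 0.1)`).
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("focal", "weighted_ce", "ce"),
                        gamma = 2, alpha = 0.25,
                        class_weights = c(0.9, 0.1)) {
  kind <- match.arg(kind)
  stopifnot(gamma >= 0, alpha >= 0, alpha <= 1,
            length(class_weights) == 2, all(class_weights >= 0))
  structure(list(kind = kind, gamma = gamma, alpha = alpha,
                 class_weights = as.numeric(class_weights)),
            class = "loss_config")
}

.clamp_p <- function(p, eps = 1e-7) {
  if (any(p <= 0 | p >= 1)) {
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

#' Focal loss
#'
#' Per-example focal loss, vectorised over examples; see [loss_config()]
#' for the exact form. Probabilities at exactly 0 or 1 are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted probability of class 1, in (0, 1).
#' @param y Binary labels (1 = pre-miRNA, 0 = not).
#' @param cfg A [loss_config()].
#' @param reduce Return the batch mean (default) rather than per-example
#'   losses.
#' @return Nonnegative loss value(s).
#' @examples
#' focal_loss(0.9, 1, loss_config(gamma = 2, alpha = 0.25))
#' @export
focal_loss <- function(p, y, cfg = loss_config(), reduce = TRUE) {
  p <- .clamp_p(p)
  py <- ifelse(y == 1, p, 1 - p)
  ay <- ifelse(y == 1, cfg$alpha, 1 - cfg$alpha)
  l <- (1 - py)^cfg$gamma * (-ay * log(py))
  if (reduce) mean(l) else l
}

#' Class-weighted cross-entropy
#'
#' `-w_y * log(p_y)` with class weights `(w_pos, w_neg)`; `w = c(1, 1)`
#' gives plain cross-entropy.
#'
#' @inheritParams focal_loss
#' @return Nonnegative loss value(s).
#' @export
weighted_ce <- function(p, y, cfg = loss_config(kind = "weighted_ce"),
                        reduce = TRUE) {
  p <- .clamp_p(p)
  py <- ifelse(y == 1, p, 1 - p)
  wy <- ifelse(y == 1, cfg$class_weights[1], cfg$class_weights[2])
  l <- -wy * log(py)
  if (reduce) mean(l) else l
}

# Dispatch on cfg$kind; used by the trainer.
compute_loss <- function(p, y, cfg, reduce = TRUE) {
  switch(cfg$kind,
    focal = focal_loss(p, y, cfg, reduce),
    weighted_ce = weighted_ce(p, y, cfg, reduce),
    ce = weighted_ce(p, y, loss_config(kind = "weighted_ce",
                                       class_weights = c(1, 1)), reduce))
}

# d(mean loss)/dp, analytic; verified against numerical differentiation in
# the test suite. Returns the gradient of the *sum*; the caller divides by
# the batch size for mean reduction.
loss_grad_p <- function(p, y, cfg) {
  p <- .clamp_p(p)
  if (cfg$kind == "focal") {
    g <- cfg$gamma
    a <- cfg$alpha
    pos <- a * (g * (1 - p)^(g - 1) * log(p) - (1 - p)^g / p)
    neg <- (1 - a) * (g * p^(g - 1) * (-log(1 - p)) + p^g / (1 - p))
    if (g == 0) {
      # (1-p)^(g-1) etc. are Inf at the boundary when g = 0; the g*... term
      # vanishes analytically, so drop it.
      pos <- a * (-1 / p)
      neg <- (1 - a) * (1 / (1 - p))
    }
    ifelse(y == 1, pos, neg)
  } else {
    w <- if (cfg$kind == "weighted_ce") cfg$class_weights else c(1, 1)
    ifelse(y == 1, -w[1] / p, w[2] / (1 - p))
  }
}
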