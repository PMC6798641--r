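#' Training protocol configuration
#'
#' Optimisation and evaluation-protocol hyperparameters: Adam with
#' mini-batches of 128 at learning rate 0.001, 300 training epochs, 10% of
#' the data held out as a test set and five-fold stratified
#' cross-validation on the remainder.
#'
#' @param batch_size Examples per optimisation step (default 128).
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training passes over the data (default 300).
#' @param n_folds Cross-validation folds (default 5).
#' @param test_fraction Held-out test share (default 0.10).
#' @param loss A [loss_config()] (default focal loss, gamma 2, alpha 0.25).
#' @param seed RNG seed driving the split, initialisation, shuffling and
#'   dropout (default 42).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabiliser (standard defaults 0.9 / 0.999 / 1e-8).
#' @param early_stop_patience If set, stop when the validation loss has
#'   not improved for this many epochs; off (`NULL`) by default — the
#'   reference protocol trains for the full epoch budget.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128, learning_rate = 0.001,
                         epochs = 300, n_folds = 5, test_fraction = 0.10,
                         loss = loss_config(), seed = 42,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, early_stop_patience = NULL) {
  stopifnot(batch_size >= 2, learning_rate > 0, epochs >= 1, n_folds >= 2,
            test_fraction >= 0, test_fraction < 1)
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, n_folds = n_folds,
                 test_fraction = test_fraction, loss = loss, seed = seed,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps,
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

get_labels <- function(x) {
  lab <- if (inherits(x, "encoded_hairpins")) x$label else x$label
  if (is.null(lab) || any(is.na(lab))) {
    abort("all records must carry a 0/1 label", class = "premir_format_error")
  }
  as.integer(lab)
}

#' Stratified test/cross-validation split
#'
#' Splits labeled data into a held-out test set and `n_folds`
#' cross-validation folds, stratified by class: within each class the
#' shuffled indices are dealt round-robin to the folds, so fold class
#' counts differ by at most one. Seeded and reproducible.
#'
#' @param x A labeled hairpin dataset tibble or `encoded_hairpins` object.
#' @param cfg A [train_config()]; uses `seed`, `test_fraction`, `n_folds`.
#' @return A `premir_split` list: `test` (integer indices) and `folds`, a
#'   list of `list(train, val)` index pairs partitioning the non-test data.
#' @export
split_dataset <- function(x, cfg = train_config()) {
  y <- get_labels(x)
  set.seed(cfg$seed)
  test <- integer(0)
  fold_of <- rep(NA_integer_, length(y))
  for (cls in c(1L, 0L)) {
    idx <- sample(which(y == cls))
    if (length(idx) < cfg$n_folds) {
      abort(sprintf("class %d has %d members, fewer than n_folds = %d",
                    cls, length(idx), cfg$n_folds),
        class = "premir_format_error")
    }
    n_test <- round(cfg$test_fraction * length(idx))
    test <- c(test, idx[seq_len(n_test)])
    pool <- idx[setdiff(seq_along(idx), seq_len(n_test))]
    fold_of[pool] <- rep_len(seq_len(cfg$n_folds), length(pool))
  }
  cv_pool <- which(!is.na(fold_of))
  folds <- purrr::map(seq_len(cfg$n_folds), function(f) {
    val <- cv_pool[fold_of[cv_pool] == f]
    list(train = sort(setdiff(cv_pool, val)), val = sort(val))
  })
  structure(list(test = sort(test), folds = folds, n = length(y)),
            class = "premir_split")
}

new_adam <- function(n, cfg) {
  list(m = numeric(n), v = numeric(n), t = 0,
       b1 = cfg$adam_beta1, b2 = cfg$adam_beta2, eps = cfg$adam_eps,
       lr = cfg$learning_rate)
}

adam_step <- function(state, theta, grad) {
  state$t <- state$t + 1
  state$m <- state$b1 * state$m + (1 - state$b1) * grad
  state$v <- state$b2 * state$v + (1 - state$b2) * grad^2
  mhat <- state$m / (1 - state$b1^state$t)
  vhat <- state$v / (1 - state$b2^state$t)
  list(state = state, theta = theta - state$lr * mhat / (sqrt(vhat) + state$eps))
}

# loss (data term + L2 on FC weights) and parameter gradients for a batch
batch_loss_grads <- function(model, encb, losscfg) {
  y <- encb$label
  fwd <- nn_forward(model, encb, train = TRUE)
  nb <- length(y)
  data_loss <- compute_loss(fwd$prob, y, losscfg)
  lam <- model$cfg$l2_lambda
  l2 <- lam * (sum(model$params$W1^2) + sum(model$params$W2^2))
  dlp <- loss_grad_p(fwd$prob, y, losscfg) / nb
  grads <- nn_backward(model, fwd$cache, dlp)
  list(loss = data_loss + l2, grads = grads, cache = fwd$cache,
       prob = fwd$prob)
}

#' Train the hairpin classifier
#'
#' Fits the cascaded CNN-BLSTM on encoded, labeled examples with Adam and
#' the configured loss, shuffling mini-batches every epoch. All
#' randomness (initialisation, shuffling, dropout) derives from
#' `train_cfg$seed`, so single-threaded runs are bit-reproducible.
#'
#' @param enc An `encoded_hairpins` object with labels.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param validation Optional `encoded_hairpins` object scored after every
#'   epoch; its loss and seven metrics are recorded in the trace.
#' @param verbose Print a line per epoch.
#' @return A `premir_fit` object with elements `model`, `trace` (a tibble
#'   with one row per epoch), `train_cfg`. Use [predict()] to score new
#'   data and [evaluate_model()] for the metric suite.
#' @export
train_network <- function(enc, model_cfg = model_config(),
                          train_cfg = train_config(), validation = NULL,
                          verbose = FALSE) {
  y <- get_labels(enc)
  n <- length(enc)
  set.seed(train_cfg$seed)
  model <- init_model(model_cfg, enc$L)
  theta <- flatten_params(model$params)
  opt <- new_adam(length(theta), train_cfg)
  trace <- vector("list", train_cfg$epochs)
  best_val <- Inf
  stale <- 0
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    # a trailing singleton cannot be batch-normalised; merge it backwards
    last <- length(batches)
    if (last > 1 && length(batches[[last]]) < 2) {
      batches[[last - 1]] <- c(batches[[last - 1]], batches[[last]])
      batches[[last]] <- NULL
    }
    ep_loss <- 0
    for (bidx in batches) {
      res <- batch_loss_grads(model, enc[bidx], train_cfg$loss)
      if (!is.finite(res$loss)) {
        abort(sprintf("loss diverged (%.3g) at epoch %d; try a lower learning rate",
                      res$loss, epoch),
          class = "premir_training_error")
      }
      model <- update_running(model, res$cache)
      upd <- adam_step(opt, theta, flatten_params(res$grads))
      opt <- upd$state
      theta <- upd$theta
      model$params <- unflatten_params(theta, model$params)
      ep_loss <- ep_loss + res$loss * length(bidx)
    }
    ep_loss <- ep_loss / n
    row <- tibble::tibble(epoch = epoch, train_loss = ep_loss,
                          loss = NA_real_, se = NA_real_, sp = NA_real_,
                          ppv = NA_real_, f_score = NA_real_,
                          g_mean = NA_real_, auroc = NA_real_,
                          aupr = NA_real_)
    if (!is.null(validation)) {
      vp <- predict_probs(model, validation)
      vy <- get_labels(validation)
      row$loss <- compute_loss(vp, vy, train_cfg$loss)
      row[, c("se", "sp", "ppv", "f_score", "g_mean", "auroc", "aupr")] <-
        metrics_report(vp, vy)
    }
    trace[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.5f%s", epoch, ep_loss,
                      if (!is.null(validation))
                        sprintf("  val loss %.5f  auroc %.4f",
                                row$loss, row$auroc) else ""))
    }
    if (!is.null(train_cfg$early_stop_patience) && !is.null(validation)) {
      if (row$loss < best_val - 1e-8) {
        best_val <- row$loss
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= train_cfg$early_stop_patience) {
          trace <- trace[seq_len(epoch)]
          break
        }
      }
    }
  }
  structure(list(model = model, trace = dplyr::bind_rows(trace),
                 train_cfg = train_cfg),
            class = "premir_fit")
}

# Eval-mode probabilities in memory-bounded chunks.
predict_probs <- function(model, enc, chunk = 512) {
  n <- length(enc)
  probs <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    probs[idx] <- nn_forward(model, enc[idx], train = FALSE)$prob
  }
  probs
}

#' Predict hairpin probabilities
#'
#' @param object A `premir_fit`.
#' @param newdata An `encoded_hairpins` object, or a hairpin dataset
#'   tibble with structures (encoded automatically at the model's pad
#'   length).
#' @param threshold Decision threshold for the hard call (default 0.5;
#'   scores at the threshold are called positive).
#' @param ... Unused.
#' @return A tibble with `id`, `.prob` and `.pred`.
#' @export
predict.premir_fit <- function(object, newdata, threshold = 0.5, ...) {
  enc <- if (inherits(newdata, "encoded_hairpins")) {
    newdata
  } else {
    encode_dataset(newdata, L = object$model$L)
  }
  if (enc$L != object$model$L) {
    abort(sprintf("encoded pad length %d != model pad length %d",
                  enc$L, object$model$L),
      class = "premir_shape_error")
  }
  p <- predict_probs(object$model, enc)
  tibble::tibble(id = enc$id, .prob = p, .pred = as.integer(p >= threshold))
}

#' Evaluate a fitted model on labeled examples
#'
#' Eval-mode forward pass (dropout off, aggregated batch-norm statistics)
#' followed by the full seven-metric report.
#'
#' @param fit A `premir_fit`.
#' @param enc A labeled `encoded_hairpins` object.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row metrics tibble (see [metrics_report()]).
#' @export
evaluate_model <- function(fit, enc, threshold = 0.5) {
  if (length(enc) == 0) abort("empty evaluation set",
                              class = "premir_format_error")
  y <- get_labels(enc)
  p <- predict_probs(fit$model, enc)
  metrics_report(p, y, threshold)
}

#' Stratified k-fold cross-validation
#'
#' Holds out `test_fraction` of the data, trains one model per fold on the
#' remaining folds (scoring the fold's validation split after every
#' epoch), and aggregates the per-fold metric reports by unweighted mean.
#'
#' @param enc A labeled `encoded_hairpins` object.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]; `n_folds` and `test_fraction`
#'   control the split, `seed` makes the whole procedure reproducible.
#' @param verbose Print per-epoch progress.
#' @return A `premir_cv` object: `fold_metrics` (tibble, one row per
#'   fold), `mean_metrics` (one row), `fits` (list of `premir_fit`),
#'   `split` (the `premir_split`).
#' @export
cross_validate <- function(enc, model_cfg = model_config(),
                           train_cfg = train_config(), verbose = FALSE) {
  split <- split_dataset(enc, train_cfg)
  fold_rows <- vector("list", train_cfg$n_folds)
  fits <- vector("list", train_cfg$n_folds)
  for (f in seq_len(train_cfg$n_folds)) {
    fold <- split$folds[[f]]
    fit <- train_network(enc[fold$train], model_cfg, train_cfg,
                         validation = enc[fold$val], verbose = verbose)
    rep <- evaluate_model(fit, enc[fold$val])
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), rep)
    fits[[f]] <- fit
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  mean_metrics <- dplyr::summarise(fold_metrics,
                                   dplyr::across(-"fold", mean))
  structure(list(fold_metrics = fold_metrics, mean_metrics = mean_metrics,
                 fits = fits, split = split),
            class = "premir_cv")
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a versioned bundle of the trained weights, the batch
#' norm running statistics, both configuration objects and the training
#' trace.
#'
#' @param fit A `premir_fit`.
#' @param path Destination file.
#' @return `path` invisibly for `save_model()`; a `premir_fit` for
#'   `load_model()`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "premir_fit"))
  bundle <- list(format = "premirnet-checkpoint", format_version = 1L,
                 package_version = as.character(utils::packageVersion("premirnet")),
                 fit = fit)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "premirnet-checkpoint")) {
    abort("not a premirnet checkpoint", class = "premir_format_error")
  }
  if (bundle$format_version > 1L) {
    abort("checkpoint written by a newer package version",
      class = "premir_format_error")
  }
  bundle$fit
}

#' @export
print.premir_fit <- function(x, ...) {
  cat(sprintf("<premir_fit> %d epochs, %d parameters, final train loss %.5f\n",
              nrow(x$trace), length(flatten_params(x$model$params)),
              x$trace$train_loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
print.premir_cv <- function(x, ...) {
  cat(sprintf("<premir_cv> %d folds\n", nrow(x$fold_metrics)))
  print(x$mean_metrics)
  invisible(x)
}

#' Tidy a fitted classifier's training trace
#'
#' @param x A `premir_fit`.
#' @param ... Unused.
#' @return The per-epoch trace tibble.
#' @export
tidy.premir_fit <- function(x, ...) x$trace

#' One-row summary of a fit
#'
#' @param x A `premir_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, parameter count, final
#'   training loss, and the final validation metrics when available.
#' @export
glance.premir_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(epochs = nrow(x$trace),
                 n_params = length(flatten_params(x$model$params)),
                 train_loss = last$train_loss, val_loss = last$loss,
                 val_auroc = last$auroc)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `premir_cv`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.premir_cv <- function(x, ...) x$fold_metrics

#' Mean cross-validation metrics
#'
#' @param x A `premir_cv`.
#' @param ... Unused.
#' @return A one-row tibble of fold-averaged metrics.
#' @export
glance.premir_cv <- function(x, ...) x$mean_metrics
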