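test_that("stratified splitting preserves class ratios and partitions", {
  ds <- simulate_hairpins(synthetic_params(n_pos = 100,
                                           imbalance_ratio = 7.4,
                                           seed = 61), fold = FALSE)
  cfg <- train_config(seed = 61)
  sp <- split_dataset(ds, cfg)
  y <- ds$label
  # 10% test, stratified
  expect_equal(sum(y[sp$test] == 1), 10)
  expect_equal(sum(y[sp$test] == 0), 74)
  # folds partition the non-test pool
  pool <- setdiff(seq_len(nrow(ds)), sp$test)
  val_union <- sort(unlist(lapply(sp$folds, `[[`, "val")))
  expect_equal(val_union, sort(pool))
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_equal(sort(c(f$train, f$val)), sort(pool))
    # stratification within +-1 example per class
    expect_lte(abs(sum(y[f$val] == 1) - 90 / 5), 1)
  }
  # determinism
  sp2 <- split_dataset(ds, cfg)
  expect_identical(sp, sp2)
  # a class smaller than the fold count is an error
  tiny <- ds[c(which(y == 1)[1:3], which(y == 0)[1:20]), ]
  expect_error(split_dataset(tiny, train_config(n_folds = 5)),
               class = "premir_format_error")
})

test_that("the per-epoch trace records loss and the seven metrics", {
  enc <- tiny_encoded(n_pos = 10, ratio = 1, seed = 62)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8, seed = 62),
                       validation = enc)
  expect_equal(nrow(fit$trace), 2)
  expect_true(all(c("loss", "se", "sp", "ppv", "f_score", "g_mean",
                    "auroc", "aupr") %in% names(fit$trace)))
  expect_true(all(is.finite(fit$trace$loss)))
})

test_that("training reduces the loss on an easy separable problem", {
  enc <- tiny_encoded(n_pos = 20, ratio = 1, seed = 63, mutation = 0)
  fit <- train_network(enc, tiny_model_config(dropout_p = 0.2),
                       train_config(epochs = 20, batch_size = 16,
                                    seed = 63))
  expect_lt(fit$trace$train_loss[20], fit$trace$train_loss[1])
})

test_that("identical seeds give bitwise-identical fits", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 64)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 64)
  f1 <- train_network(enc, tiny_model_config(), cfg)
  f2 <- train_network(enc, tiny_model_config(), cfg)
  expect_identical(premirnet:::flatten_params(f1$model$params),
                   premirnet:::flatten_params(f2$model$params))
  expect_identical(f1$trace$train_loss, f2$trace$train_loss)
})

test_that("prediction is stable, thresholded, and shape-checked", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 65)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8, seed = 65))
  p1 <- predict(fit, enc)
  p2 <- predict(fit, enc)
  expect_identical(p1, p2)
  expect_named(p1, c("id", ".prob", ".pred"))
  expect_equal(p1$.pred, as.integer(p1$.prob >= 0.5))

  # a dataset tibble is encoded on the fly at the model pad length
  ds <- simulate_hairpins(synthetic_params(n_pos = 3, imbalance_ratio = 1,
                                           seed = 66))
  ds <- ds[nchar(ds$seq) <= fit$model$L, ]
  pd <- predict(fit, ds)
  expect_equal(nrow(pd), nrow(ds))
})

test_that("evaluation demands labels and a non-empty set", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 67)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8, seed = 67))
  rep1 <- evaluate_model(fit, enc)
  expect_identical(rep1, evaluate_model(fit, enc))
  expect_error(evaluate_model(fit, enc[integer(0)]),
               class = "premir_format_error")
  unl <- enc
  unl$label <- rep(NA_integer_, length(enc))
  expect_error(evaluate_model(fit, unl), class = "premir_format_error")
})

test_that("cross-validation aggregates fold reports by unweighted mean", {
  enc <- tiny_encoded(n_pos = 12, ratio = 1, seed = 68)
  cv <- cross_validate(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8,
                                    n_folds = 2, seed = 68))
  expect_equal(nrow(cv$fold_metrics), 2)
  expect_equal(cv$mean_metrics$se, mean(cv$fold_metrics$se))
  expect_equal(cv$mean_metrics$auroc, mean(cv$fold_metrics$auroc))
  expect_length(cv$fits, 2)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv), cv$mean_metrics)
})

test_that("checkpoints round-trip through save and load", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 69)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 1, batch_size = 8, seed = 69))
  f <- tempfile(fileext = ".rds")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(predict(back, enc), predict(fit, enc))
  saveRDS(list(format = "something_else"), f)
  expect_error(load_model(f), class = "premir_format_error")
})

test_that("tidy and glance methods summarise fits", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 70)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8, seed = 70),
                       validation = enc)
  expect_identical(tidy(fit), fit$trace)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_gt(g$n_params, 0)
  expect_true(is.finite(g$val_auroc))
})

test_that("autoplot methods return ggplot objects", {
  enc <- tiny_encoded(n_pos = 8, ratio = 1, seed = 71)
  fit <- train_network(enc, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 8, seed = 71),
                       validation = enc)
  expect_s3_class(autoplot(fit), "ggplot")
  p <- predict(fit, enc)
  expect_s3_class(plot_roc(p$.prob, enc$label), "ggplot")
  expect_s3_class(plot_pr(p$.prob, enc$label), "ggplot")
})
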