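test_that("confusion counts follow the threshold rule", {
  cc <- confusion(c(0.9, 0.2), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # boundary: a score exactly at the threshold is called positive
  expect_equal(confusion(0.5, 1)$TP, 1L)
  cc0 <- confusion(rep(0, 7), rep(0, 7))
  expect_equal(cc0$TN, 7L)
  expect_error(confusion(numeric(0), numeric(0)),
               class = "premir_format_error")
})

test_that("confusion matches a brute-force count on random data", {
  set.seed(41)
  s <- runif(50)
  y <- rbinom(50, 1, 0.3)
  cc <- confusion(s, y, threshold = 0.4)
  ref <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:50) {
    pred <- s[i] >= 0.4
    ref <- ref + c(TP = pred && y[i] == 1, TN = !pred && y[i] == 0,
                   FP = pred && y[i] == 0, FN = !pred && y[i] == 1)
  }
  expect_equal(unlist(unclass(cc)), ref)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 50)
})

test_that("threshold metrics implement the five formulas", {
  perfect <- classification_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(se = 1, sp = 1, ppv = 1, f_score = 1,
                                  g_mean = 1))
  m <- classification_metrics(list(TP = 30, TN = 50, FP = 10, FN = 10))
  expect_equal(m$se, 30 / 40)
  expect_equal(m$sp, 50 / 60)
  expect_equal(m$ppv, 30 / 40)
  expect_equal(m$f_score, 60 / 80)
  expect_equal(m$g_mean^2, m$se * m$sp, tolerance = 1e-12)
  # zero-denominator convention: reported as 0 and flagged
  z <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_equal(z$ppv, 0)
  expect_true("ppv" %in% attr(z, "undefined"))
})

test_that("AUROC: separation, ties, and oracle equivalence", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    s <- round(runif(n), 2)  # rounded scores force ties
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(auroc(s, y), auroc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(runif(5), rep(1, 5)), class = "premir_metric_error")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(43)
  s <- runif(60)
  y <- rbinom(60, 1, 0.3)
  y[1:2] <- c(0, 1)
  base <- auroc(s, y)
  expect_equal(auroc(qlogis(s), y), base)
  expect_equal(auroc(s^3, y), base)
  expect_equal(auroc(rank(s), y), base)
})

test_that("AUROC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  s <- runif(200)
  y <- rbinom(200, 1, 0.25)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(s, y), ref, tolerance = 1e-10)
})

test_that("random scores give AUROC near 0.5 and AUPR near prevalence", {
  set.seed(45)
  n <- 10000
  s <- runif(n)
  y <- rbinom(n, 1, 0.12)
  expect_lt(abs(auroc(s, y) - 0.5), 0.02)
  expect_lt(abs(aupr(s, y) - mean(y)), 0.02)
})

test_that("AUPR: perfect ranking, oracle equivalence, prevalence bound", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(46)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    s <- round(runif(n), 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(aupr(s, y), aupr_oracle(s, y), tolerance = 1e-12)
  }
  # ranking all positives above some negative keeps AUPR above prevalence
  s <- c(0.9, 0.85, 0.8, 0.7, 0.2, 0.1)
  y <- c(1, 1, 0, 0, 0, 0)
  expect_gte(aupr(s, y), mean(y))
})

test_that("relative improvement reproduces benchmark-style arithmetic", {
  expect_equal(relative_improvement(0.995, 0.903), 10.19)
  expect_equal(relative_improvement(0.990, 0.911), 8.67)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_error(relative_improvement(0.5, 0), class = "premir_metric_error")
})

test_that("metrics_report combines threshold and ranking metrics", {
  set.seed(47)
  s <- runif(30)
  y <- c(0, 1, rbinom(28, 1, 0.5))
  rep <- metrics_report(s, y)
  expect_named(rep, c("se", "sp", "ppv", "f_score", "g_mean", "auroc",
                      "aupr"))
  expect_equal(rep$auroc, auroc(s, y))
  cc <- confusion(s, y)
  expect_equal(rep$f_score,
               2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
})

test_that("bundled benchmark tables load with the expected shape", {
  bm <- benchmark_table("metrics")
  expect_equal(nrow(bm), 30)
  expect_true(all(c("dataset", "split", "method", "se", "g_mean") %in%
                    names(bm)))
  counts <- benchmark_table("counts")
  expect_equal(nrow(counts), 3)
  expect_true(all(counts$positives > 0))
})

test_that("ROC and PR curve tables are consistent with the areas", {
  set.seed(48)
  s <- runif(50)
  y <- c(0, 1, rbinom(48, 1, 0.4))
  rc <- roc_curve(s, y)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1)
  # trapezoid over the ROC points equals the rank-based AUROC
  expect_equal(sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2),
               auroc(s, y), tolerance = 1e-12)
  pc <- pr_curve(s, y)
  expect_equal(sum(diff(c(0, pc$recall)) * pc$precision), aupr(s, y),
               tolerance = 1e-12)
})
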