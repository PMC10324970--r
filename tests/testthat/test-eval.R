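test_that("confusion summaries count one-vs-rest cells that sum to n", {
  y_true <- c(0, 0, 1, 1, 2)
  y_pred <- c(0, 1, 1, 1, 0)
  cs <- confusion_summary(y_true, y_pred)
  expect_equal(nrow(cs), 3L)
  expect_true(all(cs$TP + cs$FP + cs$TN + cs$FN == 5))
  expect_equal(cs$TP, c(1, 2, 0))
  expect_error(confusion_summary(integer(0), integer(0)), "empty")
})

test_that("metrics match the binary hand case and the perfect case", {
  # binary: TP=9, FN=1, TN=8, FP=2 -> sens .9, spec .8, acc .85
  y_true <- c(rep(1, 10), rep(0, 10))
  y_pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  cs <- confusion_summary(y_true, y_pred)
  m <- classification_metrics(cs, average = "micro")
  expect_equal(m$accuracy, 0.85)
  # class-1-as-positive row carries the stated cells
  r1 <- cs[cs$class == 1, ]
  expect_equal(r1$TP / (r1$TP + r1$FN), 0.9)
  expect_equal(r1$TN / (r1$TN + r1$FP), 0.8)
  perfect <- classification_metrics(confusion_summary(0:4, 0:4))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
})

test_that("macro metrics equal a brute-force per-class computation", {
  set.seed(1)
  for (rep in 1:10) {
    y_true <- sample(0:14, 300, replace = TRUE)
    y_pred <- ifelse(runif(300) < 0.6, y_true, sample(0:14, 300, replace = TRUE))
    cs <- confusion_summary(y_true, y_pred, n_classes = 15L)
    m <- suppressMessages(classification_metrics(cs))
    sen <- spe <- numeric(0)
    for (cl in 0:14) {
      tp <- sum(y_true == cl & y_pred == cl)
      fn <- sum(y_true == cl & y_pred != cl)
      tn <- sum(y_true != cl & y_pred != cl)
      fp <- sum(y_true != cl & y_pred == cl)
      if (tp + fn > 0) sen <- c(sen, tp / (tp + fn))
      if (tn + fp > 0) spe <- c(spe, tn / (tn + fp))
    }
    expect_equal(m$sensitivity, mean(sen), tolerance = 1e-12)
    expect_equal(m$specificity, mean(spe), tolerance = 1e-12)
    expect_equal(m$accuracy, mean(y_true == y_pred), tolerance = 1e-12)
  }
})

test_that("detection rate behaves at its anchors and equals macro recall", {
  expect_equal(gdr(0:9, 0:9), 100)
  set.seed(2)
  rates <- replicate(1000, {
    y_true <- sample(0:14, 60, replace = TRUE)
    y_pred <- sample(0:14, 60, replace = TRUE)
    gdr(y_true, y_pred)
  })
  expect_lt(abs(mean(rates) - 100 / 15), 2)
  y_true <- sample(0:4, 100, replace = TRUE)
  y_pred <- sample(0:4, 100, replace = TRUE)
  m <- classification_metrics(confusion_summary(y_true, y_pred, 5L))
  expect_equal(gdr(y_true, y_pred), 100 * m$sensitivity, tolerance = 1e-12)
})

test_that("cross-validation honours its contracts", {
  fm <- blob_features(n_per = 10, n_classes = 2, d = 3, sep = 0, seed = 3)
  # constant-majority classifier scores the majority fraction
  fm$labels <- c(rep(0L, 14), rep(1L, 6))
  majority <- function(xtr, ytr, xte) {
    rep(as.integer(names(which.max(table(ytr)))), nrow(xte))
  }
  r <- crossval(fm, majority, folds = 2L, seed = 1L)
  expect_equal(r$acc, 70, tolerance = 5)
  # leave-one-out on a tiny set runs
  fm2 <- blob_features(n_per = 4, n_classes = 2, d = 2, sep = 6, seed = 4)
  r2 <- crossval(fm2, "knn", folds = nrow(fm2$x), seed = 1L)
  expect_gte(r2$acc, 90)
  # reproducible fold assignment
  ra <- crossval(fm2, "knn", folds = 2L, seed = 9L)
  rb <- crossval(fm2, "knn", folds = 2L, seed = 9L)
  expect_identical(ra, rb)
  # classes smaller than the fold count are refused by name
  fm3 <- feature_matrix(matrix(rnorm(12), 6, 2), c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_error(crossval(fm3, "knn", folds = 3L), "class 1")
})

test_that("all registry classifiers learn separable blobs", {
  fm <- blob_features(n_per = 15, n_classes = 3, d = 4, sep = 7, seed = 5)
  for (clf in c("svm", "nbc", "knn", "adaboost", "lssvm_linear",
                "lssvm_poly", "lssvm_hybrid")) {
    r <- crossval(fm, clf, folds = 3L, seed = 1L)
    expect_gte(r$acc, 80)
  }
  expect_error(crossval(fm, "nope", folds = 3L), "valid")
})

test_that("the benchmark report handles empty and invalid method sets", {
  ts <- fast_trialset()
  empty <- run_benchmark(ts, methods = character(0))
  expect_s3_class(empty, "benchmark_report")
  expect_equal(nrow(empty), 0L)
  expect_error(run_benchmark(ts, methods = "strategy9"), "valid keys")
})

test_that("a strategy-1 benchmark has the two-row-by-four-classifier shape", {
  ts0 <- fast_trialset()
  keep <- trial_labels(ts0) %in% 0:2
  sub <- trialset(ts0$trials[keep], n_classes = 3L)
  rep1 <- run_benchmark(sub, methods = "strategy1", folds = 3L, seed = 1L,
                        ica = FALSE)
  expect_equal(nrow(rep1), 8L)            # 2 feature rows x 4 classifiers
  expect_setequal(unique(rep1$method), c("graph", "graph+entropy"))
  expect_setequal(unique(rep1$classifier), c("svm", "adaboost", "nbc", "knn"))
  expect_true(all(rep1$acc >= 0 & rep1$acc <= 100))
  expect_true(all(rep1$sen >= 0 & rep1$sen <= 100))
})
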