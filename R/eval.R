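#' One-vs-rest confusion summary
#'
#' Per-class TP/FP/TN/FN counts treating each class in turn as positive.
#' For every class the four counts sum to the total number of predictions.
#'
#' @param y_true,y_pred 0-based integer label vectors of equal length.
#' @param n_classes Number of classes (default inferred).
#' @return A `confusion_summary` data.frame with columns
#'   `class, TP, FP, TN, FN`.
#' @export
confusion_summary <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty predictions")
  n_classes <- n_classes %||% (max(y_true, y_pred) + 1L)
  rows <- lapply(seq_len(n_classes) - 1L, function(cl) {
    data.frame(class = cl,
               TP = sum(y_true == cl & y_pred == cl),
               FP = sum(y_true != cl & y_pred == cl),
               TN = sum(y_true != cl & y_pred != cl),
               FN = sum(y_true == cl & y_pred != cl))
  })
  structure(do.call(rbind, rows), class = c("confusion_summary", "data.frame"))
}

#' Sensitivity, specificity and accuracy from a confusion summary
#'
#' Sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` are macro-averaged
#' over one-vs-rest classes (`average = "micro"` pools the counts first);
#' accuracy is the overall fraction of correct predictions. Classes with an
#' undefined metric (zero denominator) are dropped from the macro average
#' with a message.
#'
#' @param cs A [confusion_summary()].
#' @param average `"macro"` (default) or `"micro"`.
#' @return List with `sensitivity`, `specificity`, `accuracy` in `[0, 1]`.
#' @export
classification_metrics <- function(cs, average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(inherits(cs, "confusion_summary"))
  total <- cs$TP[1L] + cs$FP[1L] + cs$TN[1L] + cs$FN[1L]
  acc <- sum(cs$TP) / total
  if (average == "micro") {
    sen <- sum(cs$TP) / sum(cs$TP + cs$FN)
    spe <- sum(cs$TN) / sum(cs$TN + cs$FP)
  } else {
    sen_i <- cs$TP / (cs$TP + cs$FN)
    spe_i <- cs$TN / (cs$TN + cs$FP)
    if (anyNA(sen_i) || anyNA(spe_i))
      message("classes with undefined metrics dropped from macro average")
    sen <- mean(sen_i, na.rm = TRUE)
    spe <- mean(spe_i, na.rm = TRUE)
  }
  list(sensitivity = sen, specificity = spe, accuracy = acc)
}

#' Good detection rate
#'
#' Defined here as the macro-averaged per-class recall (detection rate),
#' reported as a percentage. Classes absent from `y_true` are excluded.
#'
#' @param y_true,y_pred 0-based label vectors.
#' @return Scalar percentage in `[0, 100]`.
#' @export
gdr <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  present <- sort(unique(y_true))
  rec <- vapply(present, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1))
  100 * mean(rec)
}

# --- baseline classifier registry -------------------------------------------
# Each entry: function(xtr, ytr, xte) -> 0-based integer predictions.
baseline_classifier <- function(spec) {
  if (is.function(spec)) return(spec)
  switch(spec,
    svm = function(xtr, ytr, xte) {
      keep <- apply(xtr, 2L, stats::sd) > 0
      fit <- e1071::svm(xtr[, keep, drop = FALSE], factor(ytr),
                        kernel = "radial", scale = TRUE)
      as.integer(as.character(predict(fit, xte[, keep, drop = FALSE])))
    },
    nbc = function(xtr, ytr, xte) {
      keep <- apply(xtr, 2L, stats::sd) > 0
      fit <- e1071::naiveBayes(xtr[, keep, drop = FALSE], factor(ytr))
      as.integer(as.character(predict(fit, xte[, keep, drop = FALSE])))
    },
    knn = function(xtr, ytr, xte) {
      ctr <- colMeans(xtr); scl <- pmax(apply(xtr, 2L, stats::sd), 1e-12)
      xtr <- scale(xtr, ctr, scl); xte <- scale(xte, ctr, scl)
      as.integer(as.character(class::knn(xtr, xte, factor(ytr),
                                         k = min(5L, nrow(xtr)))))
    },
    adaboost = function(xtr, ytr, xte) adaboost_samme(xtr, ytr, xte),
    lssvm_hybrid = lssvm_classifier(kernel_mode = "hybrid"),
    lssvm_linear = lssvm_classifier(kernel_mode = "linear"),
    lssvm_poly = lssvm_classifier(kernel_mode = "poly"),
    lssvm_hybrid_tuned = function(xtr, ytr, xte) {
      # the combined-kernel machine with its parameters assessed by particle
      # swarm search on the training fold, per the strategy-4 recipe
      ctr <- colMeans(xtr)
      scl <- pmax(apply(xtr, 2L, stats::sd), 1e-12) * sqrt(ncol(xtr))
      xtr <- scale(xtr, ctr, scl); xte <- scale(xte, ctr, scl)
      tn <- tune_lssvm(xtr, ytr, folds = 4L, swarm_size = 10L,
                       iterations = 8L, seed = 2L)
      predict(tn$model, xte)
    },
    stop("unknown classifier '", spec, "'; valid: svm, nbc, knn, adaboost, ",
         "lssvm_hybrid, lssvm_linear, lssvm_poly, lssvm_hybrid_tuned")
  )
}

# LS-SVM baseline closure: standardises features (scaled so ||p|| is O(1),
# which keeps the polynomial and RBF kernel magnitudes comparable) and sets
# the RBF width by the median-distance heuristic on the training fold.
lssvm_classifier <- function(kernel_mode, gamma_reg = 10) {
  function(xtr, ytr, xte) {
    ctr <- colMeans(xtr); scl <- pmax(apply(xtr, 2L, stats::sd), 1e-12) * sqrt(ncol(xtr))
    xtr <- scale(xtr, ctr, scl); xte <- scale(xte, ctr, scl)
    med2 <- stats::median(stats::dist(xtr)^2)
    k <- switch(kernel_mode,
                hybrid = hybrid_kernel(a = 0.5, sigma2 = med2 / 2, order = 2L),
                linear = hybrid_kernel(a = 0, sigma2 = 1, order = 1L),
                poly = hybrid_kernel(a = 0, sigma2 = 1, order = 2L))
    fit <- lssvm_multiclass_fit(xtr, ytr, k, gamma_reg)
    predict(fit, xte)
  }
}

# SAMME AdaBoost over depth-1 rpart trees.
adaboost_samme <- function(xtr, ytr, xte, rounds = 40L) {
  n <- nrow(xtr)
  K <- length(unique(ytr))
  w <- rep(1 / n, n)
  d_tr <- data.frame(y = factor(ytr), xtr)
  d_te <- data.frame(xte)
  names(d_te) <- names(d_tr)[-1L]
  votes <- matrix(0, nrow(xte), K, dimnames = list(NULL, levels(d_tr$y)))
  for (r in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., d_tr, weights = w,
                        control = rpart::rpart.control(maxdepth = 2L, cp = 0,
                                                       minsplit = 4L, xval = 0L))
    pr_tr <- predict(fit, d_tr, type = "class")
    err <- sum(w * (pr_tr != d_tr$y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pr_tr != d_tr$y))
    w <- w / sum(w)
    pr_te <- predict(fit, d_te, type = "class")
    votes[cbind(seq_len(nrow(xte)), as.integer(pr_te))] <-
      votes[cbind(seq_len(nrow(xte)), as.integer(pr_te))] + alpha
    if (err < 1e-8) break
  }
  as.integer(colnames(votes)[max.col(votes, ties.method = "first")])
}

#' Stratified cross-validation of a classifier on a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param classifier A name known to the baseline registry (`"svm"`,
#'   `"adaboost"`, `"nbc"`, `"knn"`, `"lssvm_hybrid"`, `"lssvm_linear"`,
#'   `"lssvm_poly"`) or a `function(xtr, ytr, xte)` returning predictions.
#' @param folds Number of stratified folds (default 5; `folds = n` gives
#'   leave-one-out).
#' @param seed Seed for the fold assignment.
#' @return A one-row data.frame: `sen, spe, acc, gdr` (percent, mean over
#'   folds) and their `_sd` columns.
#' @export
crossval <- function(fm, classifier, folds = 5L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  counts <- table(y)
  if (any(counts < if (folds >= length(y)) 1L else folds) && folds < length(y)) {
    small <- names(counts)[counts < folds]
    stop("class ", small[1L], " has fewer members than folds")
  }
  folds <- min(folds, length(y))
  fold_id <- if (folds >= length(y)) seq_along(y) else
    stratified_folds(y, folds, seed = seed)
  clf <- baseline_classifier(classifier)
  per_fold <- lapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    # fold-local seeding keeps stochastic classifiers reproducible
    pred <- with_seed(seed + 7919L * f,
                      clf(fm$x[tr, , drop = FALSE], y[tr], fm$x[!tr, , drop = FALSE]))
    cs <- confusion_summary(y[!tr], pred, n_classes = max(y) + 1L)
    m <- suppressMessages(classification_metrics(cs))
    c(sen = m$sensitivity * 100, spe = m$specificity * 100,
      acc = m$accuracy * 100, gdr = gdr(y[!tr], pred))
  })
  M <- do.call(rbind, per_fold)
  out <- as.data.frame(t(c(colMeans(M), apply(M, 2L, stats::sd))))
  names(out) <- c("sen", "spe", "acc", "gdr",
                  "sen_sd", "spe_sd", "acc_sd", "gdr_sd")
  out
}

#' Run the benchmark over strategies and classifiers
#'
#' Executes the requested strategy pipelines on a trialset and reports
#' cross-validated sensitivity, specificity, accuracy and detection rate per
#' (method, classifier) row, mirroring the standard table layout:
#' strategy 1 rows (`graph`, `graph+entropy`) x (SVM, AdaBoost, NBC, KNN);
#' strategy 2 rows (`ltsa`, `llc`) x BBN-ELM; strategy 3 ablation rows x
#' the four baseline classifiers; strategy 4 rows (`lmd`, `fcm`, `lmd-fcm`)
#' x (linear, polynomial, hybrid LS-SVM).
#'
#' @param ts A [trialset()].
#' @param methods Character subset of
#'   `c("strategy1", "strategy2", "strategy3", "strategy4")` (empty gives an
#'   empty report).
#' @param folds CV folds (default 5).
#' @param seed Seed for folds and stochastic fits.
#' @param strategy3_ablations Ablation rows for strategy 3 (default
#'   `c("de", "ewt", "de-fcm-ewt")` to keep runs short; all seven accepted).
#' @param reduce_dim,reduce_k Manifold parameters for strategy 2.
#' @param ica Apply [ica_preprocess()] first (default TRUE).
#' @return A `benchmark_report` data.frame with columns
#'   `method, classifier, sen, spe, acc, gdr` and their `_sd` companions.
#' @export
run_benchmark <- function(ts, methods = c("strategy1", "strategy2", "strategy3",
                                          "strategy4"),
                          folds = 5L, seed = 1L,
                          strategy3_ablations = c("de", "ewt", "de-fcm-ewt"),
                          reduce_dim = 10L, reduce_k = 12L, ica = TRUE) {
  known <- c("strategy1", "strategy2", "strategy3", "strategy4")
  if (length(methods) > 0L && !all(methods %in% known))
    stop("unknown method key; valid keys: ", paste(known, collapse = ", "))
  empty <- data.frame(method = character(0), classifier = character(0))
  if (length(methods) == 0L)
    return(structure(empty, class = c("benchmark_report", "data.frame")))
  if (ica) ts <- suppressWarnings(ica_preprocess(ts, seed = seed))
  rows <- list()
  add <- function(method, classifier, fm, clf = classifier) {
    r <- crossval(fm, clf, folds = folds, seed = seed)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(method = method, classifier = classifier), r)
  }
  base_clf <- c("svm", "adaboost", "nbc", "knn")
  if ("strategy1" %in% methods) {
    fm_w <- graph_entropy_features(ts, include = "weights")
    fm_e <- graph_entropy_features(ts, include = "entropy")
    for (clf in base_clf) {
      add("graph", clf, fm_w)
      add("graph+entropy", clf, fm_e)
    }
  }
  if ("strategy2" %in% methods) {
    P <- trial_features(ts)
    Ps <- scale(P$x)
    Ps[, !is.finite(colSums(Ps))] <- 0
    d <- min(reduce_dim, ncol(Ps) - 1L)
    k <- min(reduce_k, nrow(Ps) - 1L)
    bbn <- function(xtr, ytr, xte) {
      fit <- fit_bbn_elm(xtr, ytr, topology = c(24L, 16L), seed = seed)
      predict(fit, xte)
    }
    Q1 <- ltsa(Ps, d = d, k = k)$Q
    add("ltsa", "bbn_elm", feature_matrix(Q1, P$labels), clf = bbn)
    mix <- llc_fit_mixture(Ps, m = 4L, d = min(d, 5L), seed = seed)
    Q2 <- llc_align(Ps, mix, d = d, k = k)$Q
    add("llc", "bbn_elm", feature_matrix(Q2, P$labels), clf = bbn)
  }
  if ("strategy3" %in% methods) {
    for (abl in strategy3_ablations) {
      fm <- strategy3_features(ts, ablation = abl)
      for (clf in base_clf) add(abl, clf, fm)
    }
  }
  if ("strategy4" %in% methods) {
    fm_lmd <- suppressWarnings(lmd_feature_matrix(ts))
    fm_base <- trial_features(ts)
    C <- min(ts$n_classes, nrow(fm_base$x) - 1L)
    enc <- function(fm) {
      Xs <- scale(fm$x)
      Xs[, !is.finite(colSums(Xs))] <- 0
      fcm <- fuzzy_cmeans(Xs, C = C, seed = seed)
      fcm_encode(feature_matrix(Xs, fm$labels), fcm)
    }
    variants <- list(`lmd` = fm_lmd, `fcm` = enc(fm_base), `lmd-fcm` = enc(fm_lmd))
    for (v in names(variants)) {
      for (clf in c("lssvm_linear", "lssvm_poly", "lssvm_hybrid_tuned"))
        add(v, clf, variants[[v]])
    }
  }
  structure(do.call(rbind, rows), class = c("benchmark_report", "data.frame"))
}

#' @export
print.benchmark_report <- function(x, digits = 2, ...) {
  cat("Benchmark report (percent, mean over folds)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y[, c("method", "classifier", "sen", "spe", "acc", "gdr")], row.names = FALSE)
  invisible(x)
}
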