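test_that("LMD reconstruction is exact and products factorise exactly", {
  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(256)
    d <- suppressWarnings(lmd_decompose(x, max_pf = 4))
    recon <- d$residual
    for (pf in d$pfs) {
      recon <- recon + pf$pf
      expect_lt(max(abs(pf$pf - pf$envelope * pf$fm)), 1e-10)
      expect_true(all(pf$envelope >= 0))
      expect_true(all(abs(pf$fm) <= 1 + 1e-12))
    }
    expect_lt(max(abs(recon - x)), 1e-8 * max(1, sd(x)))
  }
})

test_that("LMD recovers the envelope of a known AM-FM signal", {
  tt <- (0:999) / 1000
  env_true <- 1 + 0.5 * cos(2 * pi * 5 * tt)
  x <- env_true * cos(2 * pi * 80 * tt)
  d <- suppressWarnings(lmd_decompose(x, smooth_span = 11))
  trim <- 51:950                          # 5% edges removed
  r <- cor(d$pfs[[1]]$envelope[trim], env_true[trim])
  expect_gt(r, 0.95)
})

test_that("degenerate signals decompose trivially", {
  # strictly monotone input has no extrema: zero PFs, residual = input
  x <- seq(0, 1, length.out = 100)
  d <- lmd_decompose(x)
  expect_length(d$pfs, 0L)
  expect_equal(d$residual, x)
  expect_error(lmd_decompose(rnorm(10)), "length")
})

test_that("instantaneous frequency of a pure tone is recovered within 1 Hz", {
  tt <- (0:999) / 1000
  x <- cos(2 * pi * 80 * tt)
  d <- suppressWarnings(lmd_decompose(x, smooth_span = 11))
  fi <- instantaneous_frequency(d$pfs[[1]]$fm, 1000)
  expect_lt(abs(mean(fi[51:949]) - 80), 1)
})

test_that("LMD feature vectors have fixed length with zero padding", {
  ts <- fast_trialset()
  tr <- ts$trials[[1]]
  v <- suppressWarnings(lmd_features(tr, n_pf = 3))
  expect_length(v, ncol(tr$samples) * 3 * 5)
  # zero signal gives a zero vector of the same length
  z <- trial(matrix(0, 100, 2) + 0, fs = 1000, label = 0L)
  z$samples[1, 1] <- 0                    # keep finite, all-zero
  vz <- suppressWarnings(lmd_features(z, n_pf = 2))
  expect_equal(unname(vz), rep(0, 2 * 2 * 5))
})

test_that("fuzzy C-means partitions separated blobs exactly", {
  set.seed(2)
  A <- matrix(rnorm(40 * 2), 40, 2)
  B <- matrix(rnorm(40 * 2), 40, 2) + 10  # 10 SD separation
  X <- rbind(A, B)
  res <- fuzzy_cmeans(X, C = 2, seed = 1)
  hard <- max.col(res$memberships)
  truth <- rep(1:2, each = 40)
  acc <- max(mean(hard == truth), mean(hard == 3 - truth))
  expect_equal(acc, 1.0)
  centers <- res$centers[order(res$centers[, 1]), ]
  expect_lt(max(abs(centers[1, ] - colMeans(A))), 0.1)
  expect_lt(max(abs(centers[2, ] - colMeans(B))), 0.1)
})

test_that("memberships are row-stochastic and the objective never increases", {
  set.seed(3)
  for (rep in 1:20) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    res <- fuzzy_cmeans(X, C = 3, seed = rep)
    expect_equal(rowSums(res$memberships), rep(1, 30), tolerance = 1e-10)
    expect_true(all(res$memberships >= 0 & res$memberships <= 1))
    expect_true(all(diff(res$objective) <= 1e-8))
  }
})

test_that("the FCM objective agrees with an established implementation", {
  # e1071::cmeans as independent cross-check: both should reach the same
  # partition (up to label switching) on well-separated data
  set.seed(4)
  X <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(30 * 2), 30, 2) + 8)
  mine <- fuzzy_cmeans(X, C = 2, m_exp = 2, seed = 1)
  ref <- e1071::cmeans(X, centers = 2, m = 2)
  perm_err <- min(
    max(abs(mine$centers - ref$centers)),
    max(abs(mine$centers[2:1, ] - ref$centers)))
  expect_lt(perm_err, 0.05)
})

test_that("FCM encoding respects the limit rule and the concat width", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  res <- fuzzy_cmeans(X, C = 3, seed = 1)
  fm <- feature_matrix(rbind(res$centers[2, ], X), c(0L, rep(1L, 30)))
  enc <- fcm_encode(fm, res, mode = "memberships")
  expect_equal(unname(enc$x[1, 2]), 1)    # a point at a centre is all-in
  enc2 <- fcm_encode(fm, res, mode = "concat")
  expect_equal(ncol(enc2$x), 4 + 3)
  # deterministic given the frozen centres
  expect_identical(enc2$x, fcm_encode(fm, res, mode = "concat")$x)
})

test_that("hybrid kernel values match direct evaluation and limits", {
  expect_equal(hybrid_kernel_eval(hybrid_kernel(a = 1, sigma2 = 2), c(1, 2), c(1, 2)), 1)
  expect_equal(hybrid_kernel_eval(hybrid_kernel(a = 0, order = 1), c(1, 1), c(1, 1)), 3)
  set.seed(6)
  k <- hybrid_kernel(a = 0.5, sigma2 = 1.3, order = 3)
  for (rep in 1:100) {
    p <- rnorm(4); q <- rnorm(4)
    direct <- 0.5 * exp(-sum((p - q)^2) / (2 * 1.3)) + 0.5 * (sum(p * q) + 1)^3
    expect_equal(hybrid_kernel_eval(k, p, q), direct, tolerance = 1e-12)
  }
  # a outside [0,1] is rejected
  expect_error(hybrid_kernel(a = 1.2), "mixing")
})

test_that("hybrid Gram matrices are PSD and the a = {0,1} limits are pure", {
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    a <- runif(1); s2 <- runif(1, 0.2, 4); O <- sample(1:3, 1)
    K <- hybrid_kernel_matrix(hybrid_kernel(a, s2, O), X)
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K)))
  }
  X <- matrix(rnorm(15 * 2), 15, 2)
  Krbf <- hybrid_kernel_matrix(hybrid_kernel(1, 0.7, 2), X)
  d2 <- as.matrix(dist(X))^2
  expect_equal(Krbf, exp(-d2 / (2 * 0.7)), tolerance = 1e-12, ignore_attr = TRUE)
  Kpoly <- hybrid_kernel_matrix(hybrid_kernel(0, 0.7, 2), X)
  expect_equal(Kpoly, (X %*% t(X) + 1)^2, tolerance = 1e-12)
})

test_that("the LS-SVM solves its KKT system and classic toys", {
  set.seed(8)
  # KKT residual on random problems
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(c(-1, 1), 40, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    fit <- lssvm_fit(X, y, hybrid_kernel(0.5, 1, 2), gamma_reg = 5)
    expect_lt(fit$residual, 1e-8)
  }
  # XOR with an RBF kernel
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(1, 1, -1, -1)
  fx <- lssvm_fit(Xx, yx, hybrid_kernel(a = 1, sigma2 = 0.5), gamma_reg = 100)
  expect_equal(predict(fx, Xx), yx)
  # gamma -> 0: alphas vanish and prediction collapses to the bias sign
  X2 <- matrix(rnorm(30 * 2), 30, 2)
  y2 <- c(rep(1, 20), rep(-1, 10))
  f0 <- lssvm_fit(X2, y2, hybrid_kernel(1, 1, 1), gamma_reg = 1e-10)
  expect_lt(max(abs(f0$alphas)), 1e-6)
  expect_true(all(predict(f0, X2) == sign(f0$bias)))
})

test_that("one-vs-one multiclass voting is consistent and symmetric", {
  fm <- blob_features(n_per = 15, n_classes = 3, d = 4, sep = 8, seed = 9)
  k <- hybrid_kernel(0.5, 2, 2)
  fit <- lssvm_multiclass_fit(fm$x, fm$labels, k, gamma_reg = 10)
  expect_equal(mean(predict(fit, fm$x) == fm$labels), 1.0)
  # with two classes the multiclass wrapper equals the binary machine
  sel <- fm$labels < 2
  X2 <- fm$x[sel, ]; y2 <- fm$labels[sel]
  m2 <- lssvm_multiclass_fit(X2, y2, k, 10)
  b2 <- lssvm_fit(X2, ifelse(y2 == 0, 1, -1), k, 10)
  expect_equal(predict(m2, X2), ifelse(predict(b2, X2) == 1, 0, 1))
  # permuting class labels permutes predictions identically
  perm <- c(2L, 0L, 1L)
  fitp <- lssvm_multiclass_fit(fm$x, perm[fm$labels + 1L], k, 10)
  expect_equal(predict(fitp, fm$x), perm[predict(fit, fm$x) + 1L])
})

test_that("kernel tuning returns the collapsed point and beats random draws", {
  fm <- blob_features(n_per = 12, n_classes = 3, d = 4, sep = 5, seed = 10)
  pt <- list(a = c(0.5, 0.5), log_sigma2 = c(1, 1), log_gamma = c(2, 2),
             order = c(2, 2))
  res <- tune_lssvm(fm$x, fm$labels, folds = 3, bounds = pt,
                    swarm_size = 3, iterations = 2, seed = 1)
  expect_equal(res$params$a, 0.5)
  expect_equal(res$params$sigma2, exp(1))
  expect_equal(res$params$order, 2)
  # tuned CV error is no worse than the median of random parameter draws
  set.seed(11)
  tuned <- tune_lssvm(fm$x, fm$labels, folds = 3, swarm_size = 6,
                      iterations = 4, seed = 2)
  rand_err <- replicate(10, {
    k <- hybrid_kernel(runif(1), exp(runif(1, -2, 6)), sample(1:3, 1))
    g <- exp(runif(1, -2, 6))
    fold <- semgkit:::stratified_folds(fm$labels, 3, seed = 7)
    mean(vapply(1:3, function(f) {
      m <- lssvm_multiclass_fit(fm$x[fold != f, ], fm$labels[fold != f], k, g)
      mean(predict(m, fm$x[fold == f, , drop = FALSE]) != fm$labels[fold == f])
    }, numeric(1)))
  })
  expect_lte(tuned$cv_error, median(rand_err))
})
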