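test_that("spurious correlation coefficient follows its closed form", {
  c0 <- list(C = 0L); c1 <- list(C = 1L)
  expect_identical(spurious_coefficient(c0, 0.99), 1)
  expect_identical(spurious_coefficient(c0, -0.3), 1)
  expect_equal(spurious_coefficient(c1, 0.8), 0.2, tolerance = 1e-12)
  expect_equal(spurious_coefficient(c1, -0.6), 0.4, tolerance = 1e-12)
  expect_error(spurious_coefficient(c1, 1.5), "pcc")
})

test_that("vertex and graph entropy match their closed forms and a brute force", {
  # all incident weights 1 -> 0; two 0.5 edges -> ln 2; zero weights drop out
  R1 <- matrix(1, 3, 3); diag(R1) <- 0
  expect_equal(vertex_entropy(R1, 1), 0, tolerance = 1e-12)
  R2 <- matrix(0, 3, 3); R2[1, 2] <- R2[2, 1] <- 0.5; R2[1, 3] <- R2[3, 1] <- 0.5
  expect_equal(vertex_entropy(R2, 1), log(2), tolerance = 1e-12)
  # vertex entropies {ln 2, (ln 2)/2, (ln 2)/2} sum to 2 ln 2
  expect_equal(graph_entropy(R2), 2 * log(2), tolerance = 1e-12)
  expect_equal(graph_entropy(matrix(0, 4, 4)), 0)
  # brute-force double loop over the weight matrix on random graphs
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    R <- matrix(runif(n * n), n, n); R <- (R + t(R)) / 2; diag(R) <- 0
    brute <- 0
    for (i in 1:n) for (j in 1:n) if (j != i && R[i, j] > 0)
      brute <- brute - R[i, j] * log(R[i, j])
    expect_equal(graph_entropy(R), brute, tolerance = 1e-12)
  }
})

test_that("entropy is bounded by the -R log R maximum and is relabel-invariant", {
  set.seed(1)
  n <- 6
  R <- matrix(runif(n * n), n, n); R <- (R + t(R)) / 2; diag(R) <- 0
  for (i in 1:n) expect_lte(vertex_entropy(R, i), (n - 1) * exp(-1))
  expect_lte(graph_entropy(R), n * (n - 1) * exp(-1))
  perm <- sample(n)
  expect_equal(graph_entropy(R[perm, perm]), graph_entropy(R), tolerance = 1e-12)
})

test_that("the Granger test agrees with an established implementation", {
  skip_if_not_installed("lmtest")
  set.seed(8)
  for (rep in 1:10) {
    p <- generate_pair_causal(300, beta = runif(1, 0, 0.8), seed = rep)
    mine <- granger_causal(p$x, p$y, max_lag = 1)   # fixed lag for comparison
    ref <- lmtest::grangertest(p$y ~ p$x, order = 1)
    expect_equal(mine$prob, ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("the Granger test rejects degenerate input", {
  expect_error(granger_causal(rep(1, 100), rnorm(100)), "constant")
  expect_error(granger_causal(rnorm(100), rnorm(99)), "length")
})

test_that("dynamic graphs separate coupled from independent channel pairs", {
  set.seed(3)
  n <- 1000
  # two independent channels: weights should sit at 1 in most intervals
  X <- matrix(rnorm(n * 2), n, 2)
  tr <- trial(X, fs = 1000, label = 0L)
  dg <- build_dynamic_graph(tr, plan = plan_windows(n, 250), max_lag = 4)
  w <- vapply(dg$graphs, function(R) R[1, 2], numeric(1))
  expect_gte(mean(w == 1), 0.5)
  # delayed near-copy: strong causality and |pcc| ~ 1 -> weight near 0
  # (min edge mode: the causal direction dominates the edge)
  x <- as.numeric(stats::filter(rnorm(n + 1), 0.98, method = "recursive"))
  ch1 <- x[2:(n + 1)]
  ch2 <- x[1:n] + rnorm(n, sd = 0.01)    # ch2 lags ch1 by one sample
  tr2 <- trial(cbind(ch1, ch2), fs = 1000, label = 0L)
  dg2 <- build_dynamic_graph(tr2, plan = plan_windows(n, 500), max_lag = 4,
                             edge_mode = "min")
  w2 <- vapply(dg2$graphs, function(R) R[1, 2], numeric(1))
  expect_lt(mean(w2), 0.2)
  # a single-window plan gives a length-1 graph sequence
  dg3 <- build_dynamic_graph(tr, plan = plan_windows(n, n), max_lag = 2)
  expect_length(dg3$graphs, 1L)
})

test_that("independent channels yield weight-1 edges in most intervals", {
  # Monte-Carlo over trials: C = 0 dominates, so the weight is exactly 1 in
  # about (1 - alpha)^2 = 90% of intervals (both directions must accept)
  set.seed(5)
  hits <- replicate(100, {
    X <- matrix(rnorm(500 * 2), 500, 2)
    tr <- trial(X, fs = 1000, label = 0L)
    dg <- build_dynamic_graph(tr, plan = plan_windows(500, 250), max_lag = 2)
    vapply(dg$graphs, function(R) R[1, 2] == 1, logical(1))
  })
  expect_gte(mean(hits), 0.85)
  expect_lt(abs(mean(hits) - 0.95^2), 0.06)
})

test_that("entropy feature vectors have the documented layout and symmetry", {
  set.seed(2)
  g1 <- matrix(runif(9), 3, 3); g1 <- (g1 + t(g1)) / 2; diag(g1) <- 0
  dg <- structure(list(graphs = list(g1), plan = NULL, edge_mode = "mean"),
                  class = "dynamic_graph")
  f <- entropy_features(dg)
  expect_length(f, 1 * (1 + 3))
  # permuting vertex labels permutes the per-vertex block, fixes the graph block
  perm <- c(2, 3, 1)
  dgp <- structure(list(graphs = list(g1[perm, perm]), plan = NULL,
                        edge_mode = "mean"), class = "dynamic_graph")
  fp <- entropy_features(dgp)
  expect_equal(fp[1], f[1], ignore_attr = TRUE)
  expect_equal(unname(fp[2:4]), unname(f[2:4][perm]))
})

test_that("entropy features separate coupled synthetic classes", {
  ts <- fast_trialset()
  keep <- trial_labels(ts) %in% c(0L, 1L)
  sub <- trialset(ts$trials[keep], n_classes = 2L)
  fm <- graph_entropy_features(sub, max_lag = 4)
  X <- fm$x; y <- fm$labels
  inter <- mean(as.matrix(dist(rbind(colMeans(X[y == 0, ]), colMeans(X[y == 1, ]))))[1, 2])
  intra <- mean(c(dist(X[y == 0, ]), dist(X[y == 1, ])))
  expect_gt(inter, 0)            # classes have distinct centroids
  acc <- crossval(fm, "knn", folds = 4L, seed = 1L)$acc
  expect_gt(acc, 80)
})
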