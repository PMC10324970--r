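test_that("an all-zero RBM gives hidden probability one half everywhere", {
  r <- rbm_new(4, 3, seed = 1)
  r$W[] <- 0; r$c[] <- 0
  p <- semgkit:::rbm_hidden_prob(r, matrix(runif(8), 2, 4))
  expect_equal(as.numeric(p), rep(0.5, 6))
})

test_that("CD-1 training learns a repeated binary pattern", {
  set.seed(2)
  pat <- matrix(rep(c(1, 0, 1, 1, 0, 0), each = 8), 8, 6)
  r <- rbm_new(6, 4, lr = 0.2, seed = 3)
  for (i in 1:500) r <- rbm_cd1_step(r, pat)
  ph <- semgkit:::rbm_hidden_prob(r, pat)
  recon <- semgkit:::rbm_visible_prob(r, ph)
  expect_lt(mean(abs(recon - pat)), 0.05)
})

test_that("CD-1 rejects inputs outside the unit interval", {
  r <- rbm_new(3, 2)
  expect_error(rbm_cd1_step(r, matrix(c(0.5, 1.2, 0), 1, 3)), "\\[0,1\\]")
})

test_that("the CD-1 update aligns with the exact likelihood gradient", {
  # brute-force oracle: enumerate all states of a 3-visible/2-hidden RBM
  set.seed(4)
  hits <- logical(100)
  for (draw in 1:100) {
    W <- matrix(rnorm(6, sd = 0.5), 3, 2)
    a <- rnorm(3, sd = 0.5); cc <- rnorm(2, sd = 0.5)
    V <- matrix(as.numeric(runif(64 * 3) < 0.5), 64, 3)
    r <- structure(list(W = W, a = a, c = cc, lr = 1), class = "rbm")
    r2 <- rbm_cd1_step(r, V)
    upd <- c(r2$W - W, r2$a - a, r2$c - cc)
    g <- exact_rbm_gradient(W, a, cc, V)
    hits[draw] <- sum(upd * c(g$W, g$a, g$c)) > 0
  }
  expect_gte(mean(hits), 0.9)
})

test_that("greedy pretraining stacks layers consistently", {
  set.seed(5)
  X <- matrix(runif(40 * 6), 40, 6)
  stack0 <- pretrain_bbn(X, c(6, 4), epochs = 0, seed = 1)
  expect_length(stack0, 1L)
  expect_identical(dim(stack0[[1]]$W), c(6L, 4L))
  expect_error(pretrain_bbn(X, c(5, 4)), "input dimension")
  # training reduces first-layer reconstruction error vs the random init
  recon_err <- function(stack, X) {
    ph <- semgkit:::rbm_hidden_prob(stack[[1]], X)
    mean((semgkit:::rbm_visible_prob(stack[[1]], ph) - X)^2)
  }
  Xpat <- matrix(rep(diag(1, 6)[rep(1:3, length.out = 40), ]), 40, 6)
  stack1 <- pretrain_bbn(Xpat, c(6, 4), epochs = 40, lr = 0.3, seed = 1)
  st0 <- pretrain_bbn(Xpat, c(6, 4), epochs = 0, seed = 1)
  expect_lt(recon_err(stack1, Xpat), recon_err(st0, Xpat))
})

test_that("the ELM solve interpolates and has minimum norm", {
  set.seed(6)
  # square nonsingular H: exact interpolation
  H <- matrix(rnorm(100), 10, 10)
  T <- semgkit:::one_hot(sample(0:2, 10, replace = TRUE), 3)
  beta <- elm_solve(H, T)
  expect_lt(max(abs(H %*% beta - T)), 1e-8)
  # rank-deficient H: solution norm does not exceed perturbed solutions
  H2 <- cbind(H[, 1:5], H[, 1:5])     # rank 5
  beta2 <- elm_solve(H2, T)
  ns <- rbind(diag(5), -diag(5))      # null space of H2
  for (j in 1:5) {
    Z <- ns[, j] %o% rnorm(3)
    expect_lte(sqrt(sum(beta2^2)), sqrt(sum((beta2 + Z)^2)) + 1e-10)
  }
})

test_that("the belief-network ELM classifier fits separable data", {
  fm <- blob_features(n_per = 30, n_classes = 3, d = 5, sep = 8, seed = 7)
  fit <- fit_bbn_elm(fm$x, fm$labels, topology = c(16L, 8L), epochs = 10,
                     bp_epochs = 10, seed = 1)
  expect_equal(mean(predict(fit, fm$x) == fm$labels), 1.0)
  # determinism: same seed gives identical output weights
  fit2 <- fit_bbn_elm(fm$x, fm$labels, topology = c(16L, 8L), epochs = 10,
                      bp_epochs = 10, seed = 1)
  expect_identical(fit$beta, fit2$beta)
  # fine-tuning loss trace is non-increasing
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
})

test_that("a random-projection ELM alone separates two clear classes", {
  fm <- blob_features(n_per = 100, n_classes = 2, d = 4, sep = 6, seed = 8)
  fit <- fit_bbn_elm(fm$x, fm$labels, topology = c(20L), epochs = 0,
                     bp_epochs = 0, seed = 1)
  expect_gte(mean(predict(fit, fm$x) == fm$labels), 0.8)
})

test_that("PSO minimises the sphere function and respects trivial cases", {
  sphere <- function(x) sum(x^2)
  res <- pso_minimize(sphere, rep(-5, 5), rep(5, 5), swarm_size = 20,
                      iterations = 100, seed = 1)
  expect_lt(res$value, 1e-3)
  expect_true(all(diff(res$trace) <= 0))
  # degenerate bounds pin the swarm at the optimum
  res0 <- pso_minimize(sphere, rep(0, 3), rep(0, 3), swarm_size = 5,
                       iterations = 3, seed = 1)
  expect_equal(res0$value, 0)
  # non-finite objective values are rejected, not fatal
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res2 <- pso_minimize(spiky, -2, 2, swarm_size = 10, iterations = 30, seed = 2)
  expect_true(is.finite(res2$value))
})

test_that("topology search returns a usable model and sensible choices", {
  fm <- blob_features(n_per = 24, n_classes = 3, d = 6, sep = 7, seed = 9)
  # single candidate: must return that width
  res <- pso_topology_search(fm$x, fm$labels, candidate_widths = 12L,
                             depth_range = c(1L, 1L), swarm_size = 2L,
                             iterations = 1L, seed = 1, epochs = 2L,
                             bp_epochs = 0L)
  expect_equal(res$topology, 12L)
  expect_s3_class(res$model, "bbn_elm")
  expect_error(pso_topology_search(fm$x, fm$labels, candidate_widths = integer(0)),
               "non-empty")
})
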