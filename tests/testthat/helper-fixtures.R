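# Shared fixtures, generated in code.

# Small fast trialset used by several end-to-end tests; built once per run.
fast_trialset <- local({
  cache <- NULL
  function(seed = 3L) {
    if (is.null(cache)) {
      cfg <- synth_config(n_classes = 5L, trials_per_class = 12L, fs = 1000,
                          duration_s = 1, seed = seed)
      cache <<- generate_semg(cfg)
    }
    cache
  }
})

# A tiny two-trial trialset with known values.
tiny_trialset <- function(fs = 100) {
  set.seed(7)
  trialset(list(
    trial(matrix(rnorm(200 * 3), 200, 3), fs = fs, label = 0L, subject = "a"),
    trial(matrix(rnorm(200 * 3), 200, 3), fs = fs, label = 1L, subject = "b")
  ))
}

# Gaussian class blobs as a feature matrix.
blob_features <- function(n_per = 20L, n_classes = 3L, d = 5L, sep = 6,
                          seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(n_classes) - 1L, function(cl) {
    mu <- rep(0, d); mu[cl %% d + 1L] <- sep
    sweep(matrix(rnorm(n_per * d), n_per, d), 2L, mu, `+`)
  }))
  feature_matrix(X, rep(seq_len(n_classes) - 1L, each = n_per))
}

# Exact RBM log-likelihood gradient by enumeration of all hidden/visible
# states (independent oracle for the CD-1 direction check).
exact_rbm_gradient <- function(W, a, c, V) {
  nv <- length(a); nh <- length(c)
  states <- function(k) as.matrix(expand.grid(rep(list(0:1), k)))
  Hs <- states(nh)
  Vs <- states(nv)
  # positive phase: E_{p(h|v)}[v h'] averaged over data rows
  pos_W <- matrix(0, nv, nh); pos_a <- rep(0, nv); pos_c <- rep(0, nh)
  for (i in seq_len(nrow(V))) {
    v <- as.numeric(V[i, ])
    ph <- 1 / (1 + exp(-(c + as.numeric(t(W) %*% v))))
    pos_W <- pos_W + outer(v, ph)
    pos_a <- pos_a + v
    pos_c <- pos_c + ph
  }
  pos_W <- pos_W / nrow(V); pos_a <- pos_a / nrow(V); pos_c <- pos_c / nrow(V)
  # negative phase: exact model expectation over all joint states
  logp <- matrix(0, nrow(Vs), nrow(Hs))
  for (i in seq_len(nrow(Vs))) for (j in seq_len(nrow(Hs))) {
    v <- as.numeric(Vs[i, ]); h <- as.numeric(Hs[j, ])
    logp[i, j] <- sum(a * v) + sum(c * h) + as.numeric(t(v) %*% W %*% h)
  }
  p <- exp(logp - max(logp)); p <- p / sum(p)
  neg_W <- matrix(0, nv, nh); neg_a <- rep(0, nv); neg_c <- rep(0, nh)
  for (i in seq_len(nrow(Vs))) for (j in seq_len(nrow(Hs))) {
    v <- as.numeric(Vs[i, ]); h <- as.numeric(Hs[j, ])
    neg_W <- neg_W + p[i, j] * outer(v, h)
    neg_a <- neg_a + p[i, j] * v
    neg_c <- neg_c + p[i, j] * h
  }
  list(W = pos_W - neg_W, a = pos_a - neg_a, c = pos_c - neg_c)
}
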