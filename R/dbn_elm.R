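#' Create a restricted Boltzmann machine
#'
#' @param n_visible,n_hidden Layer sizes.
#' @param lr Learning rate epsilon.
#' @param seed Seed for the small random weight initialisation.
#' @return An `rbm` object with weight matrix `W` (`n_visible x n_hidden`),
#'   visible biases `a`, hidden biases `c`, and `lr`.
#' @export
rbm_new <- function(n_visible, n_hidden, lr = 0.1, seed = 1L) {
  W <- with_seed(seed, matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01),
                              n_visible, n_hidden))
  structure(list(W = W, a = numeric(n_visible), c = numeric(n_hidden), lr = lr),
            class = "rbm")
}

rbm_hidden_prob <- function(rbm, V) logistic(sweep(V %*% rbm$W, 2L, rbm$c, `+`))
rbm_visible_prob <- function(rbm, H) logistic(sweep(H %*% t(rbm$W), 2L, rbm$a, `+`))

#' One contrastive-divergence (CD-1) update
#'
#' Single Gibbs step: hidden probabilities `P(h=1|v) = sigma(c + W'v)` are
#' computed and sampled; reconstruction probabilities
#' `P(v'=1|h) = sigma(a + Wh)` and the corresponding hidden probabilities
#' close the chain. Updates, averaged over the batch:
#' `dW = lr * (<v h>_data - <v' h'>_recon)`, `da = lr * (<v> - <v'>)`,
#' `dc = lr * (<h> - <h'>)`. Visible values are treated as probabilities in
#' `[0, 1]` (no sampling of the data layer).
#'
#' @param rbm An [rbm_new()] object.
#' @param batch Matrix of visible vectors, values in `[0, 1]`.
#' @return Updated `rbm`. Uses the current RNG stream for the hidden sample;
#'   seed the stream for determinism.
#' @export
rbm_cd1_step <- function(rbm, batch) {
  batch <- as.matrix(batch)
  if (any(batch < 0 | batch > 1)) stop("batch values must lie in [0,1]")
  nb <- nrow(batch)
  ph <- rbm_hidden_prob(rbm, batch)
  hs <- matrix(as.numeric(stats::runif(length(ph)) < ph), nb)
  pv1 <- rbm_visible_prob(rbm, hs)
  ph1 <- rbm_hidden_prob(rbm, pv1)
  rbm$W <- rbm$W + rbm$lr * (crossprod(batch, ph) - crossprod(pv1, ph1)) / nb
  rbm$a <- rbm$a + rbm$lr * (colMeans(batch) - colMeans(pv1))
  rbm$c <- rbm$c + rbm$lr * (colMeans(ph) - colMeans(ph1))
  rbm
}

#' Greedy layer-wise pretraining of an RBM stack
#'
#' Trains each layer by CD-1 on the hidden probabilities of the layer below
#' (the raw data for the first layer). `topology[1]` must equal the input
#' dimensionality; subsequent entries are hidden-layer widths.
#'
#' @param X Input matrix scaled to `[0, 1]`.
#' @param topology Integer vector of layer sizes, input first.
#' @param epochs Passes over the data per layer.
#' @param lr Learning rate.
#' @param seed Integer seed (weights and hidden sampling).
#' @param batch_size Minibatch size (default 16).
#' @return List of `rbm` objects, one per adjacent layer pair.
#' @export
pretrain_bbn <- function(X, topology, epochs = 20L, lr = 0.1, seed = 1L,
                         batch_size = 16L) {
  X <- as.matrix(X)
  if (topology[1L] != ncol(X)) stop("topology[1] must equal input dimension")
  if (any(X < 0 | X > 1)) stop("X must be scaled to [0,1]")
  n_layers <- length(topology) - 1L
  stack <- vector("list", n_layers)
  H <- X
  with_seed(seed, {
    for (l in seq_len(n_layers)) {
      r <- rbm_new(topology[l], topology[l + 1L], lr = lr,
                   seed = stats::runif(1, 1, 2^30))
      if (epochs > 0L) {
        n <- nrow(H)
        for (ep in seq_len(epochs)) {
          ord <- sample(n)
          for (b in split(ord, ceiling(seq_along(ord) / batch_size)))
            r <- rbm_cd1_step(r, H[b, , drop = FALSE])
        }
      }
      stack[[l]] <- r
      H <- rbm_hidden_prob(r, H)
    }
  })
  stack
}

bbn_forward <- function(stack, X) {
  H <- as.matrix(X)
  acts <- vector("list", length(stack))
  for (l in seq_along(stack)) {
    H <- rbm_hidden_prob(stack[[l]], H)
    acts[[l]] <- H
  }
  acts
}

#' Extreme learning machine output weights
#'
#' Minimum-norm least-squares solution `beta = H^+ T` via the Moore-Penrose
#' pseudoinverse; multi-class targets are one-hot and the decision is argmax.
#'
#' @param H Hidden-layer activation matrix `n x m`.
#' @param T Target matrix `n x C` (one-hot for classification).
#' @return `beta`, an `m x C` matrix.
#' @export
elm_solve <- function(H, T) {
  H <- as.matrix(H); T <- as.matrix(T)
  if (!all(is.finite(H))) stop("H must be finite")
  MASS::ginv(H) %*% T
}

#' Fit the belief-network / ELM hybrid classifier
#'
#' Pipeline: min-max scale inputs to `[0, 1]`; greedy CD-1 pretraining of the
#' RBM stack ([pretrain_bbn()]); forward pass with logistic activations; ELM
#' solve of the output weights `beta` from the last hidden layer
#' ([elm_solve()]); optional backpropagation fine-tuning of all layer weights
#' on the squared error `(T - O)^2` with `beta` re-solved afterwards. The
#' fine-tuning step size is halved whenever a step would increase the loss,
#' so the recorded loss trace is non-increasing.
#'
#' @param X Feature matrix (rows = samples).
#' @param y 0-based integer labels.
#' @param topology Hidden-layer widths (input width is prepended
#'   automatically).
#' @param epochs Pretraining epochs per layer.
#' @param lr Pretraining learning rate.
#' @param bp_epochs Fine-tuning epochs (0 disables).
#' @param bp_lr Initial fine-tuning step size.
#' @param seed Integer seed.
#' @return A `bbn_elm` model with a [predict][predict.bbn_elm] method.
#' @export
fit_bbn_elm <- function(X, y, topology = c(32L, 16L), epochs = 20L, lr = 0.1,
                        bp_epochs = 20L, bp_lr = 0.01, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n_classes <- max(y) + 1L
  if (any(tabulate(y + 1L, n_classes) < 1L)) stop("every class needs at least one sample")
  rng <- apply(X, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-12)
  Xs <- sweep(sweep(X, 2L, rng[1L, ]), 2L, span, `/`)
  full_topology <- c(ncol(X), as.integer(topology))
  stack <- pretrain_bbn(Xs, full_topology, epochs = epochs, lr = lr, seed = seed)
  Tmat <- one_hot(y, n_classes)
  loss_trace <- numeric(0)
  if (bp_epochs > 0L) {
    res <- bbn_finetune(stack, Xs, Tmat, bp_epochs, bp_lr)
    stack <- res$stack
    loss_trace <- res$loss
  }
  H <- bbn_forward(stack, Xs)[[length(stack)]]
  beta <- elm_solve(H, Tmat)
  structure(list(stack = stack, beta = beta, topology = full_topology,
                 n_classes = n_classes, scale_min = rng[1L, ], scale_span = span,
                 loss_trace = loss_trace),
            class = "bbn_elm")
}

# Full-batch gradient descent on squared error through the logistic stack,
# with step-halving to keep the loss monotone. beta is re-solved each epoch.
bbn_finetune <- function(stack, Xs, Tmat, epochs, lr) {
  L <- length(stack)
  loss_of <- function(st) {
    H <- bbn_forward(st, Xs)[[L]]
    beta <- elm_solve(H, Tmat)
    list(loss = mean((Tmat - H %*% beta)^2), beta = beta)
  }
  cur <- loss_of(stack)
  trace <- cur$loss
  for (ep in seq_len(epochs)) {
    acts <- bbn_forward(stack, Xs)
    O <- acts[[L]] %*% cur$beta
    delta <- -(2 / length(Tmat)) * (Tmat - O) %*% t(cur$beta)   # dLoss/dH_L
    grads <- vector("list", L)
    for (l in L:1) {
      Hl <- acts[[l]]
      dz <- delta * Hl * (1 - Hl)
      Hin <- if (l == 1L) Xs else acts[[l - 1L]]
      grads[[l]] <- list(W = crossprod(Hin, dz), c = colSums(dz))
      if (l > 1L) delta <- dz %*% t(stack[[l]]$W)
    }
    repeat {
      cand <- stack
      for (l in seq_len(L)) {
        cand[[l]]$W <- cand[[l]]$W - lr * grads[[l]]$W
        cand[[l]]$c <- cand[[l]]$c - lr * grads[[l]]$c
      }
      new <- loss_of(cand)
      if (new$loss <= cur$loss + 1e-12) {
        stack <- cand; cur <- new; break
      }
      lr <- lr / 2
      if (lr < 1e-10) break
    }
    trace <- c(trace, cur$loss)
    if (lr < 1e-10) break
  }
  list(stack = stack, loss = trace)
}

#' @export
print.bbn_elm <- function(x, ...) {
  cat(sprintf("<bbn_elm> topology %s -> %d classes\n",
              paste(x$topology, collapse = "-"), x$n_classes))
  invisible(x)
}

#' Predict with a fitted belief-network/ELM model
#'
#' @param object A [fit_bbn_elm()] model.
#' @param newdata Feature matrix.
#' @param type `"class"` (0-based labels) or `"score"` (raw output matrix).
#' @param ... Unused.
#' @export
predict.bbn_elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$scale_min), 2L, object$scale_span, `/`)
  Xs[Xs < 0] <- 0; Xs[Xs > 1] <- 1
  H <- bbn_forward(object$stack, Xs)[[length(object$stack)]]
  O <- H %*% object$beta
  if (type == "score") return(O)
  max.col(O, ties.method = "first") - 1L
}

#' Global-best particle swarm optimisation
#'
#' Standard PSO: `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`,
#' positions clipped to the bounds. Candidates with non-finite objective
#' values are rejected (their personal best is not updated), so the global
#' best trace is non-increasing by construction.
#'
#' @param fn Objective function of a numeric vector, to minimise.
#' @param lower,upper Numeric bound vectors (finite, equal length).
#' @param swarm_size Particles (default 20).
#' @param iterations Iterations (default 100).
#' @param inertia Inertia weight `w` (default 0.5).
#' @param cognitive,social Acceleration weights `c1`, `c2` (default 1).
#' @param seed Integer seed.
#' @return List with `par`, `value`, and the per-iteration `trace` of the
#'   global best.
#' @export
pso_minimize <- function(fn, lower, upper, swarm_size = 20L, iterations = 100L,
                         inertia = 0.5, cognitive = 1, social = 1, seed = 1L) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) stop("bounds must be finite")
  if (swarm_size < 2L || iterations < 1L) stop("swarm_size >= 2 and iterations >= 1 required")
  d <- length(lower)
  with_seed(seed, {
    X <- matrix(stats::runif(swarm_size * d, rep(lower, each = swarm_size),
                             rep(upper, each = swarm_size)), swarm_size, d)
    V <- matrix(0, swarm_size, d)
    f <- apply(X, 1L, function(x) {
      v <- suppressWarnings(fn(x)); if (is.finite(v)) v else Inf
    })
    pbest <- X; pbest_f <- f
    g <- which.min(pbest_f)
    gbest <- pbest[g, ]; gbest_f <- pbest_f[g]
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
      r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
      V <- inertia * V + cognitive * r1 * (pbest - X) +
        social * r2 * sweep(X, 2L, gbest, function(x, g) g - x)
      X <- X + V
      X <- pmin(pmax(X, rep(lower, each = swarm_size)), rep(upper, each = swarm_size))
      f <- apply(X, 1L, function(x) {
        v <- suppressWarnings(fn(x)); if (is.finite(v)) v else Inf
      })
      better <- f < pbest_f
      pbest[better, ] <- X[better, , drop = FALSE]
      pbest_f[better] <- f[better]
      g <- which.min(pbest_f)
      if (pbest_f[g] < gbest_f) { gbest <- pbest[g, ]; gbest_f <- pbest_f[g] }
      trace[it] <- gbest_f
    }
    list(par = gbest, value = gbest_f, trace = trace)
  })
}

#' PSO search over belief-network topologies
#'
#' Encodes (depth, per-layer width index) as a continuous vector, decodes by
#' rounding into `candidate_widths`, and minimises the validation error of
#' [fit_bbn_elm()] by [pso_minimize()]. The best topology is refit on all
#' data.
#'
#' @param X,y Training data (0-based labels).
#' @param candidate_widths Integer vector of allowed layer widths.
#' @param depth_range Length-2 integer vector, e.g. `c(1, 3)`.
#' @param swarm_size,iterations,seed PSO controls (small defaults; the
#'   objective is a full model fit).
#' @param val_frac Fraction held out for validation (stratified).
#' @param ... Passed to [fit_bbn_elm()].
#' @return List with the refit `model`, `topology`, `val_error`, and the
#'   search `log` (data.frame of evaluated topologies and errors).
#' @export
pso_topology_search <- function(X, y, candidate_widths, depth_range = c(1L, 2L),
                                swarm_size = 6L, iterations = 5L, seed = 1L,
                                val_frac = 0.25, ...) {
  if (length(candidate_widths) == 0L) stop("candidate_widths must be non-empty")
  X <- as.matrix(X); y <- as.integer(y)
  max_depth <- depth_range[2L]
  folds <- stratified_folds(y, max(2L, round(1 / val_frac)), seed = seed)
  val <- folds == 1L
  log_env <- new.env()
  log_env$rows <- list()
  decode <- function(par) {
    depth <- max(depth_range[1L], min(max_depth, round(par[1L])))
    idx <- pmax(1L, pmin(length(candidate_widths), round(par[1L + seq_len(depth)])))
    candidate_widths[idx]
  }
  objective <- function(par) {
    topo <- decode(par)
    key <- paste(topo, collapse = "-")
    fit <- try(fit_bbn_elm(X[!val, , drop = FALSE], y[!val], topology = topo,
                           seed = seed, ...), silent = TRUE)
    if (inherits(fit, "try-error")) return(Inf)
    err <- mean(predict(fit, X[val, , drop = FALSE]) != y[val])
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(topology = key, val_error = err)
    err
  }
  lower <- c(depth_range[1L], rep(1, max_depth))
  upper <- c(depth_range[2L], rep(length(candidate_widths), max_depth))
  best <- pso_minimize(objective, lower, upper, swarm_size = swarm_size,
                       iterations = iterations, seed = seed)
  topo <- decode(best$par)
  model <- fit_bbn_elm(X, y, topology = topo, seed = seed, ...)
  list(model = model, topology = topo, val_error = best$value,
       log = do.call(rbind, log_env$rows))
}
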