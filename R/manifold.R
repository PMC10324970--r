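#' Local tangent space alignment (LTSA)
#'
#' Nonlinear dimensionality reduction. For each point the k nearest
#' neighbours (Euclidean) are centred and the top `d` right singular vectors
#' `V_i` give local tangent coordinates; the alignment matrix accumulates
#' `A[S_i, S_i] += C_k (I - V_i V_i^T) C_k` with `C_k` the centering matrix.
#' The embedding consists of the eigenvectors of `(A + A^T)/2` belonging to
#' the `d` smallest nonzero eigenvalues (the constant eigenvector spanning
#' the null space is discarded).
#'
#' @param P Numeric matrix, `n x D`.
#' @param d Target (intrinsic) dimensionality, `d < D`.
#' @param k Neighbourhood size, `d < k < n` (default 12).
#' @return An `embedding` object with fields `Q` (`n x d`), `method`,
#'   `eigenvalues`, and the parameters used.
#' @export
ltsa <- function(P, d, k = 12L) {
  P <- as.matrix(P)
  n <- nrow(P); D <- ncol(P)
  if (!all(is.finite(P))) stop("P must be finite")
  if (k <= d) stop("k must exceed d")
  if (k >= n) stop("k must be smaller than n")
  nb <- knn_index(P, k)
  A <- matrix(0, n, n)
  Ck <- diag(k) - matrix(1 / k, k, k)
  for (i in seq_len(n)) {
    Si <- nb[i, ]
    Xi <- P[Si, , drop = FALSE]
    Xi <- sweep(Xi, 2L, colMeans(Xi))
    sv <- svd(Xi, nu = min(k, d), nv = 0)
    if (sv$d[1L] < 1e-12) warning("degenerate neighbourhood at point ", i)
    Vi <- sv$u[, seq_len(d), drop = FALSE]
    A[Si, Si] <- A[Si, Si] + Ck %*% (diag(k) - Vi %*% t(Vi)) %*% Ck
  }
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]; vecs <- eg$vectors[, ord, drop = FALSE]
  tol <- 1e-10 * max(sum(abs(vals)), 1)
  # The null space always contains the constant vector; for noiseless or
  # disconnected data it is larger and its extra directions carry the
  # embedding. Keep the null space modulo constants, then fill up to d with
  # the smallest nonzero eigenvectors. For a connected noisy manifold this
  # reduces to "discard the constant eigenvector, take the d smallest".
  null_idx <- which(vals <= tol)
  nz_idx <- which(vals > tol)
  Qnull <- NULL
  if (length(null_idx) > 0L) {
    Vn <- vecs[, null_idx, drop = FALSE]
    ones <- rep(1 / sqrt(n), n)
    Vn <- Vn - ones %*% (t(ones) %*% Vn)
    sv <- svd(Vn)
    r <- sum(sv$d > 1e-8)
    if (r > 0L) Qnull <- sv$u[, seq_len(min(r, d)), drop = FALSE]
  }
  n_null <- if (is.null(Qnull)) 0L else ncol(Qnull)
  n_need <- d - n_null
  if (n_need > length(nz_idx)) stop("not enough nonzero eigenvalues for d = ", d)
  Q <- cbind(Qnull,
             if (n_need > 0L) vecs[, nz_idx[seq_len(n_need)], drop = FALSE])
  keep_vals <- c(rep(0, n_null), if (n_need > 0L) vals[nz_idx[seq_len(n_need)]])
  structure(list(Q = Q * sqrt(n), method = "LTSA",
                 eigenvalues = keep_vals, d = d, k = k),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %s: %d points -> %d dims\n", x$method, nrow(x$Q), ncol(x$Q)))
  invisible(x)
}

knn_index <- function(P, k) {
  n <- nrow(P)
  D2 <- as.matrix(stats::dist(P))^2
  t(vapply(seq_len(n), function(i) {
    order(D2[i, ])[2L:(k + 1L)]
  }, integer(k)))
}

#' Fit a mixture of probabilistic PCA models (LLC step 1)
#'
#' EM for a mixture of `m` probabilistic PCA models with `d`-dimensional
#' latent spaces. Returns per-sample responsibilities and per-model local
#' coordinates (posterior latent means). The log-likelihood is
#' non-decreasing across EM iterations; if a component collapses (negligible
#' responsibility mass) the fit is re-initialised, up to 3 restarts.
#'
#' @param P Numeric matrix `n x D`.
#' @param m Number of local models (>= 1).
#' @param d Latent dimensionality per model.
#' @param seed Integer seed for initialisation.
#' @param max_iter,tol EM controls.
#' @return A `local_model_mixture`: `responsibilities` (`n x m`, rows sum to
#'   1), `local_coords` (list of `n x d` matrices), `means`, `W`, `sigma2`,
#'   `loglik` trace.
#' @export
llc_fit_mixture <- function(P, m, d, seed = 1L, max_iter = 100L, tol = 1e-6) {
  P <- as.matrix(P)
  n <- nrow(P); D <- ncol(P)
  if (m < 1L) stop("m >= 1 required")
  if (n < m * (d + 1L)) stop("too few samples for m local models")
  for (restart in 0:3) {
    fit <- try(mppca_em(P, m, d, seed + restart * 1000L, max_iter, tol), silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit)
  }
  stop("mixture fitting failed after restarts: ", attr(fit, "condition")$message)
}

mppca_em <- function(P, m, d, seed, max_iter, tol) {
  n <- nrow(P); D <- ncol(P)
  init <- with_seed(seed, {
    centers <- P[sample(n, m), , drop = FALSE]
    Ws <- lapply(seq_len(m), function(j) matrix(stats::rnorm(D * d, sd = 0.1), D, d))
    list(centers = centers, Ws = Ws)
  })
  mu <- init$centers
  W <- init$Ws
  sigma2 <- rep(mean(apply(P, 2, stats::var)) / 2 + 1e-3, m)
  pi_j <- rep(1 / m, m)
  loglik <- numeric(0)
  R <- NULL
  for (it in seq_len(max_iter)) {
    # E step: responsibilities under C_j = W_j W_j' + sigma2_j I
    logd <- matrix(0, n, m)
    for (j in seq_len(m)) {
      Cj <- W[[j]] %*% t(W[[j]]) + diag(sigma2[j], D)
      ch <- chol(Cj + diag(1e-10, D))
      Xc <- sweep(P, 2L, mu[j, ])
      z <- backsolve(ch, t(Xc), transpose = TRUE)
      logd[, j] <- log(pi_j[j]) - sum(log(diag(ch))) - 0.5 * colSums(z^2) -
        0.5 * D * log(2 * pi)
    }
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    loglik <- c(loglik, sum(lse))
    R <- exp(logd - lse)
    Nj <- colSums(R)
    if (any(Nj < d + 1e-6)) stop("empty mixture component")
    # M step (per-component weighted PPCA via local covariance eigen)
    for (j in seq_len(m)) {
      mu[j, ] <- colSums(R[, j] * P) / Nj[j]
      Xc <- sweep(P, 2L, mu[j, ])
      Sj <- crossprod(sqrt(R[, j]) * Xc) / Nj[j]
      eg <- eigen(Sj, symmetric = TRUE)
      lam <- pmax(eg$values, 1e-12)
      sigma2[j] <- if (D > d) max(mean(lam[(d + 1L):D]), 1e-8) else 1e-8
      W[[j]] <- eg$vectors[, seq_len(d), drop = FALSE] %*%
        diag(sqrt(pmax(lam[seq_len(d)] - sigma2[j], 1e-12)), d)
    }
    pi_j <- Nj / n
    if (it > 1L && abs(loglik[it] - loglik[it - 1L]) < tol * abs(loglik[it - 1L] + 1)) break
  }
  # posterior latent means y_ij = M_j^{-1} W_j' (x - mu_j), M_j = W'W + sigma2 I
  coords <- lapply(seq_len(m), function(j) {
    Mj <- crossprod(W[[j]]) + diag(sigma2[j], d)
    t(solve(Mj, t(W[[j]])) %*% t(sweep(P, 2L, mu[j, ])))
  })
  structure(list(responsibilities = R, local_coords = coords, means = mu,
                 W = W, sigma2 = sigma2, weights = pi_j, loglik = loglik,
                 m = m, d = d),
            class = "local_model_mixture")
}

#' Align local linear models into a global embedding (LLC step 2)
#'
#' Computes LLE reconstruction weights `W` from k nearest neighbours (rows
#' sum to 1), forms `M = (I - W)^T (I - W)`, builds the responsibility
#' weighted block matrix `U` with blocks `u_ij = r_ij * [y_ij; 1]`
#' (homogeneous coordinate appended per local model), and solves the
#' generalized eigenproblem `B v = lambda A v` with `B = U^T M U`,
#' `A = U^T U` for the `d` smallest nonzero eigenvalues. The embedding is
#' `Q = U L` where `L` collects the eigenvectors.
#'
#' @param P Data matrix used to fit `mix`.
#' @param mix A [llc_fit_mixture()] result.
#' @param d Target dimensionality.
#' @param k Neighbourhood size for the LLE weights (default 12).
#' @return An `embedding` with extra fields `L` and `U`.
#' @export
llc_align <- function(P, mix, d, k = 12L) {
  stopifnot(inherits(mix, "local_model_mixture"))
  P <- as.matrix(P)
  n <- nrow(P)
  W <- lle_weights(P, k)
  IW <- diag(n) - W
  M <- crossprod(IW)
  m <- mix$m; dl <- mix$d
  U <- matrix(0, n, m * (dl + 1L))
  for (j in seq_len(m)) {
    block <- cbind(mix$local_coords[[j]], 1) * mix$responsibilities[, j]
    U[, ((j - 1L) * (dl + 1L) + 1L):(j * (dl + 1L))] <- block
  }
  B <- crossprod(U, M %*% U)
  A <- crossprod(U)
  sol <- generalized_eigen_smallest(B, A, d)
  L <- sol$vectors
  structure(list(Q = U %*% L, method = "LLC", eigenvalues = sol$values,
                 L = L, U = U, d = d, k = k, m = m),
            class = "embedding")
}

lle_weights <- function(P, k) {
  n <- nrow(P)
  nb <- knn_index(P, k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Zi <- sweep(P[nb[i, ], , drop = FALSE], 2L, P[i, ])
    G <- tcrossprod(Zi)
    G <- G + diag(1e-3 * sum(diag(G)) / k + 1e-12, k)
    w <- solve(G, rep(1, k))
    W[i, nb[i, ]] <- w / sum(w)
  }
  W
}

# d smallest nonzero eigenpairs of B v = lambda A v (both symmetric, A PSD).
generalized_eigen_smallest <- function(B, A, d, null_tol = 1e-10) {
  p <- nrow(A)
  A <- (A + t(A)) / 2; B <- (B + t(B)) / 2
  ridge <- 0
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * sum(diag(A)) / p + 1e-12
    message("singular A in generalized eigenproblem; ridge ", signif(ridge, 3), " added")
    ch <- chol(A + diag(ridge, p))
  }
  Li <- backsolve(ch, diag(p))             # inv(chol) so A = R'R, Li = R^{-1}
  S <- t(Li) %*% B %*% Li
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- Li %*% eg$vectors[, ord, drop = FALSE]
  tol <- null_tol * max(sum(abs(vals)), 1)
  nz <- which(vals > tol)
  if (length(nz) < d) stop("not enough nonzero generalized eigenvalues")
  keep <- nz[seq_len(d)]
  list(values = vals[keep], vectors = vecs[, keep, drop = FALSE])
}

#' Procrustes residual between two configurations
#'
#' Root-mean-square residual after optimally translating, rotating and
#' scaling `Q` onto `Y`. Used to compare embeddings, which are defined only
#' up to affine/orthogonal indeterminacy.
#'
#' @param Q,Y Configurations with matching row counts.
#' @param mode `"orthogonal"` (rigid rotation + single scale, the default) or
#'   `"affine"` (full linear map, appropriate when the embedding is defined
#'   only up to affine indeterminacy, as for tangent-space methods).
#' @return Scalar RMS residual.
#' @export
procrustes_error <- function(Q, Y, mode = c("orthogonal", "affine")) {
  mode <- match.arg(mode)
  if (mode == "affine") {
    fit <- stats::lm.fit(cbind(1, as.matrix(Q)), as.matrix(Y))
    return(sqrt(mean(fit$residuals^2)))
  }
  Q <- scale(as.matrix(Q), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  if (ncol(Q) < ncol(Y)) Q <- cbind(Q, matrix(0, nrow(Q), ncol(Y) - ncol(Q)))
  if (ncol(Y) < ncol(Q)) Y <- cbind(Y, matrix(0, nrow(Y), ncol(Q) - ncol(Y)))
  s <- svd(crossprod(Y, Q))
  R <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(Q^2)
  sqrt(mean((scl * Q %*% R - Y)^2))
}

#' Trustworthiness of an embedding
#'
#' Fraction-based measure of how much an embedding's k-neighbourhoods can be
#' trusted: penalises points that are close in the embedding but far in the
#' original space. 1 is perfect.
#'
#' @param X Original data (`n x D`).
#' @param Q Embedded data (`n x d`).
#' @param k Neighbourhood size.
#' @return Scalar in `[0, 1]`.
#' @export
trustworthiness <- function(X, Q, k = 10L) {
  n <- nrow(X)
  rx <- t(apply(as.matrix(stats::dist(X)), 1L, rank, ties.method = "first"))
  nq <- knn_index(as.matrix(Q), k)
  pen <- 0
  for (i in seq_len(n)) {
    for (j in nq[i, ]) {
      r <- rx[i, j] - 1L                  # rank among others (self has rank 1)
      if (r > k) pen <- pen + (r - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * pen
}
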