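#' Convex hybrid RBF / polynomial kernel
#'
#' `K(p, q) = a * exp(-||p - q||^2 / (2 sigma2)) + (1 - a) * ((p . q) + 1)^O`.
#' Both summands satisfy the Mercer condition, so any convex combination does
#' too: Gram matrices are symmetric positive semidefinite. `a = 1` is the
#' pure RBF kernel (unit diagonal), `a = 0` the pure polynomial kernel.
#'
#' @param a Mixing weight in `[0, 1]` (default 0.5).
#' @param sigma2 RBF width `> 0` (default 1).
#' @param order Polynomial order `>= 1` (default 2).
#' @return A `hybrid_kernel` parameter object.
#' @export
hybrid_kernel <- function(a = 0.5, sigma2 = 1, order = 2L) {
  if (a < 0 || a > 1) stop("mixing weight a must lie in [0,1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  order <- as.integer(order)
  if (order < 1L) stop("polynomial order must be >= 1")
  structure(list(a = a, sigma2 = sigma2, order = order), class = "hybrid_kernel")
}

#' Evaluate a hybrid kernel
#'
#' @param k A [hybrid_kernel()].
#' @param p,q Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
hybrid_kernel_eval <- function(k, p, q) {
  stopifnot(inherits(k, "hybrid_kernel"), length(p) == length(q))
  k$a * exp(-sum((p - q)^2) / (2 * k$sigma2)) +
    (1 - k$a) * (sum(p * q) + 1)^k$order
}

#' Gram matrix under a hybrid kernel
#'
#' @param k A [hybrid_kernel()].
#' @param X Matrix of rows `p_t`.
#' @param Y Optional second matrix (default `X`).
#' @return `nrow(X) x nrow(Y)` kernel matrix.
#' @export
hybrid_kernel_matrix <- function(k, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ip <- X %*% t(Y)
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) - 2 * ip +
    outer(rep(1, nrow(X)), rowSums(Y^2))
  k$a * exp(-pmax(d2, 0) / (2 * k$sigma2)) + (1 - k$a) * (ip + 1)^k$order
}

#' Fit a binary least-squares SVM
#'
#' Solves the LS-SVM KKT linear system
#' `[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]` for labels in
#' `{-1, +1}`; the decision function is
#' `f(p) = sign(sum_t alpha_t K(p_t, p) + b)`. A singular system gets one
#' jitter of `1e-10 * trace` before failing.
#'
#' @param X Training matrix.
#' @param y Labels in `{-1, +1}` (both classes present).
#' @param kernel A [hybrid_kernel()].
#' @param gamma_reg Regularisation `gamma > 0` (default 10).
#' @return An `lssvm` model: `alphas`, `bias`, `kernel`, `gamma_reg`,
#'   `support_data`, and the KKT `residual`.
#' @export
lssvm_fit <- function(X, y, kernel = hybrid_kernel(), gamma_reg = 10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2L)
    stop("y must contain both -1 and +1")
  if (gamma_reg <= 0) stop("gamma_reg must be positive")
  n <- nrow(X)
  K <- hybrid_kernel_matrix(kernel, X)
  M <- K + diag(1 / gamma_reg, n)
  # partitioned solve of the bordered KKT system (numerically stable for
  # any gamma): eta = M^-1 1, nu = M^-1 y, b = 1'nu / 1'eta, alpha = nu - b eta
  sol <- tryCatch(solve(M, cbind(1, y)), error = function(e) {
    solve(M + diag(1e-10 * sum(diag(M)), n), cbind(1, y))
  })
  b <- sum(sol[, 2L]) / sum(sol[, 1L])
  alpha <- sol[, 2L] - b * sol[, 1L]
  A <- rbind(c(0, rep(1, n)), cbind(1, M))
  resid <- sqrt(sum((A %*% c(b, alpha) - c(0, y))^2)) / max(sqrt(sum(y^2)), 1e-12)
  structure(list(alphas = alpha, bias = b, kernel = kernel,
                 gamma_reg = gamma_reg, support_data = X, residual = resid),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("<lssvm> %d support points, a = %.2f, sigma2 = %.3g, O = %d, gamma = %.3g\n",
              nrow(x$support_data), x$kernel$a, x$kernel$sigma2,
              x$kernel$order, x$gamma_reg))
  invisible(x)
}

#' Predict with a binary LS-SVM
#'
#' @param object An [lssvm_fit()] model.
#' @param newdata Matrix of points.
#' @param type `"class"` (signs) or `"decision"` (raw values).
#' @param ... Unused.
#' @export
predict.lssvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  Kx <- hybrid_kernel_matrix(object$kernel, as.matrix(newdata), object$support_data)
  f <- as.numeric(Kx %*% object$alphas + object$bias)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' Multi-class LS-SVM via one-vs-one voting
#'
#' Fits a binary [lssvm_fit()] for every unordered class pair; prediction is
#' by majority vote with ties broken by summed decision values. Labels are
#' 0-based integers.
#'
#' @param X Training matrix.
#' @param y 0-based integer labels (>= 2 classes).
#' @param kernel A [hybrid_kernel()].
#' @param gamma_reg Regularisation.
#' @return An `lssvm_multiclass` model.
#' @export
lssvm_multiclass_fit <- function(X, y, kernel = hybrid_kernel(), gamma_reg = 10) {
  X <- as.matrix(X)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes")
  pairs <- utils::combn(classes, 2L)
  models <- lapply(seq_len(ncol(pairs)), function(p) {
    c1 <- pairs[1L, p]; c2 <- pairs[2L, p]
    idx <- y %in% c(c1, c2)
    lssvm_fit(X[idx, , drop = FALSE], ifelse(y[idx] == c1, 1, -1),
              kernel, gamma_reg)
  })
  structure(list(models = models, pairs = pairs, classes = classes,
                 kernel = kernel, gamma_reg = gamma_reg),
            class = "lssvm_multiclass")
}

#' @export
predict.lssvm_multiclass <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  nc <- length(object$classes)
  votes <- matrix(0, n, nc, dimnames = list(NULL, object$classes))
  score <- matrix(0, n, nc, dimnames = list(NULL, object$classes))
  for (p in seq_along(object$models)) {
    c1 <- as.character(object$pairs[1L, p]); c2 <- as.character(object$pairs[2L, p])
    f <- predict(object$models[[p]], newdata, type = "decision")
    win1 <- f >= 0
    votes[win1, c1] <- votes[win1, c1] + 1
    votes[!win1, c2] <- votes[!win1, c2] + 1
    score[, c1] <- score[, c1] + f
    score[, c2] <- score[, c2] - f
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- which(votes[i, ] == max(votes[i, ]))
    out[i] <- object$classes[if (length(best) == 1L) best else
      best[which.max(score[i, best])]]
  }
  out
}

#' Tune the hybrid-kernel LS-SVM by particle swarm search
#'
#' Minimises stratified k-fold cross-validation error over
#' `(a, log sigma2, log gamma, O)` (the order is rounded when decoded) using
#' [pso_minimize()], then refits on all data at the best parameters.
#'
#' @param X,y Training data (0-based labels).
#' @param folds CV folds (default 3).
#' @param bounds List with elements `a`, `log_sigma2`, `log_gamma`, `order`,
#'   each a length-2 numeric range.
#' @param swarm_size,iterations,seed PSO controls (small defaults; each
#'   objective evaluation is a full CV).
#' @return List with `model` (refit [lssvm_multiclass_fit()]), `params`
#'   (decoded best parameters), `cv_error`.
#' @export
tune_lssvm <- function(X, y, folds = 3L,
                       bounds = list(a = c(0, 1), log_sigma2 = c(-2, 6),
                                     log_gamma = c(-2, 6), order = c(1, 3)),
                       swarm_size = 8L, iterations = 8L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = seed)
  decode <- function(par) hybrid_kernel(a = par[1L], sigma2 = exp(par[2L]),
                                        order = round(par[4L]))
  objective <- function(par) {
    k <- decode(par); g <- exp(par[3L])
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- try(lssvm_multiclass_fit(X[tr, , drop = FALSE], y[tr], k, g), silent = TRUE)
      if (inherits(m, "try-error")) return(Inf)
      mean(predict(m, X[!tr, , drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(errs)
  }
  lo <- c(bounds$a[1L], bounds$log_sigma2[1L], bounds$log_gamma[1L], bounds$order[1L])
  hi <- c(bounds$a[2L], bounds$log_sigma2[2L], bounds$log_gamma[2L], bounds$order[2L])
  best <- pso_minimize(objective, lo, hi, swarm_size = swarm_size,
                       iterations = iterations, seed = seed)
  k <- decode(best$par)
  model <- lssvm_multiclass_fit(X, y, k, exp(best$par[3L]))
  list(model = model,
       params = list(a = k$a, sigma2 = k$sigma2, order = k$order,
                     gamma_reg = exp(best$par[3L])),
       cv_error = best$value)
}
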