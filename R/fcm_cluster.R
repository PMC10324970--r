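#' Fuzzy C-means clustering
#'
#' Alternating optimisation of the fuzzy partition objective
#' `J_m = sum_i sum_j u_ij^m ||p_i - c_j||^2`: the membership matrix is
#' initialised with row-normalised uniform random numbers, then cluster
#' centres (membership-weighted means) and memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))` alternate until the objective
#' change falls below `tol` or `max_iter` is reached. A sample coincident
#' with a centre gets membership 1 there (standard limit). The objective
#' trace is non-increasing.
#'
#' @param X Data matrix `N x d`.
#' @param C Number of clusters (>= 2, < N).
#' @param m_exp Fuzzifier `m > 1` (default 2).
#' @param tol Objective-change tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @param seed Integer seed for the random initialisation.
#' @return An `fcm_result`: `centers` (`C x d`), `memberships` (`N x C`,
#'   rows sum to 1), `m_exp`, `objective` trace.
#' @export
fuzzy_cmeans <- function(X, C, m_exp = 2, tol = 1e-6, max_iter = 200L, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (C < 2L) stop("C >= 2 required")
  if (m_exp <= 1) stop("fuzzifier must exceed 1")
  if (N <= C) stop("need more samples than clusters")
  U <- with_seed(seed, {
    U0 <- matrix(stats::runif(N * C), N, C)
    U0 / rowSums(U0)
  })
  obj <- numeric(0)
  centers <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m_exp
    centers <- (t(Um) %*% X) / colSums(Um)
    D2 <- outer(rowSums(X^2), rep(1, C)) - 2 * X %*% t(centers) +
      outer(rep(1, N), rowSums(centers^2))
    D2 <- pmax(D2, 0)
    obj <- c(obj, sum(Um * D2))
    U <- fcm_memberships(D2, m_exp)
    if (it > 1L && abs(obj[it] - obj[it - 1L]) < tol) break
  }
  structure(list(centers = centers, memberships = U, m_exp = m_exp,
                 objective = obj),
            class = "fcm_result")
}

# Membership update from squared distances; zero distance -> hard membership.
fcm_memberships <- function(D2, m_exp) {
  N <- nrow(D2); C <- ncol(D2)
  U <- matrix(0, N, C)
  zero <- D2 < 1e-300
  hard <- rowSums(zero) > 0
  if (any(hard)) {
    for (i in which(hard)) U[i, which(zero[i, ])[1L]] <- 1
  }
  if (any(!hard)) {
    P <- D2[!hard, , drop = FALSE]^(-1 / (m_exp - 1))
    U[!hard, ] <- P / rowSums(P)
  }
  U
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> %d clusters, %d samples, J_m = %.4g (%d iterations)\n",
              nrow(x$centers), nrow(x$memberships), utils::tail(x$objective, 1),
              length(x$objective)))
  invisible(x)
}

#' Encode a feature matrix with fuzzy cluster memberships
#'
#' Each trial's feature row is mapped to its `C` membership degrees under the
#' frozen cluster centres of a fitted [fuzzy_cmeans()] and either concatenated
#' to the raw row (`mode = "concat"`, width `d + C`) or used alone
#' (`mode = "memberships"`).
#'
#' @param features A [feature_matrix()] with dimensionality matching the fit.
#' @param fcm An `fcm_result`.
#' @param mode `"concat"` (default) or `"memberships"`.
#' @return A [feature_matrix()].
#' @export
fcm_encode <- function(features, fcm, mode = c("concat", "memberships")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "feature_matrix"), inherits(fcm, "fcm_result"))
  X <- features$x
  if (ncol(X) != ncol(fcm$centers)) stop("feature dimension does not match FCM centers")
  C <- nrow(fcm$centers)
  D2 <- outer(rowSums(X^2), rep(1, C)) - 2 * X %*% t(fcm$centers) +
    outer(rep(1, nrow(X)), rowSums(fcm$centers^2))
  U <- fcm_memberships(pmax(D2, 0), fcm$m_exp)
  colnames(U) <- paste0("memb", seq_len(C))
  out <- if (mode == "concat") cbind(X, U) else U
  feature_matrix(out, features$labels)
}
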