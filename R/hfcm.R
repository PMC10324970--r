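#' Create a high-order fuzzy cognitive map
#'
#' An HFCM over `Nc` concept nodes with memory order `h`: the next state of
#' node `i` is `S_i(t+1) = g( sum_l sum_j W[i,j,l] S_j(t-l+1) + b_i )` with
#' `g = tanh`, so predicted states stay in `[-1, 1]`.
#'
#' @param weights Numeric array `Nc x Nc x h`; `weights[i, j, l]` is the
#'   strength of node `j`'s impact on node `i` at lag `l`.
#' @param bias Numeric vector of length `Nc`.
#' @return An `hfcm` object.
#' @export
hfcm <- function(weights, bias) {
  weights <- as.array(weights)
  if (length(dim(weights)) == 2L) dim(weights) <- c(dim(weights), 1L)
  if (length(dim(weights)) != 3L || dim(weights)[1L] != dim(weights)[2L])
    stop("weights must be an Nc x Nc x h array")
  if (length(bias) != dim(weights)[1L]) stop("bias length must equal Nc")
  structure(list(weights = weights, bias = as.numeric(bias),
                 order = dim(weights)[3L], n_nodes = dim(weights)[1L]),
            class = "hfcm")
}

#' One-step HFCM prediction
#'
#' @param model An [hfcm()].
#' @param history Matrix `Nc x h` of past states, most recent first
#'   (`history[, 1] = S(t)`, `history[, 2] = S(t-1)`, ...), entries in
#'   `[-1, 1]`. With `h = 1` this is the ordinary first-order map.
#' @return Numeric vector of length `Nc` in `[-1, 1]`.
#' @export
hfcm_predict <- function(model, history) {
  stopifnot(inherits(model, "hfcm"))
  history <- as.matrix(history)
  h <- model$order
  if (ncol(history) < h) stop("history must provide h = ", h, " past state vectors")
  if (any(abs(history) > 1 + 1e-12)) stop("states must lie in [-1, 1]")
  z <- model$bias
  for (l in seq_len(h)) z <- z + model$weights[, , l] %*% history[, l]
  as.numeric(tanh(z))
}

#' Fit an HFCM to a multivariate state series
#'
#' Ridge least squares on the tanh-linearised recurrence: for each node `i`,
#' `artanh(S_i(t+1))` is regressed on the `Nc * h` lagged states plus an
#' intercept (the intercept is not penalised). States must lie in `(-1, 1)`;
#' values at exactly +-1 are clipped inward before `artanh`.
#'
#' @param series_matrix Matrix `T x Nc` of node states over time.
#' @param h Memory order (>= 1).
#' @param ridge Ridge penalty (default 1e-3).
#' @return An [hfcm()] with extra field `rmse` (in-sample one-step RMSE on
#'   the squashed scale).
#' @export
hfcm_fit <- function(series_matrix, h = 2L, ridge = 1e-3) {
  S <- as.matrix(series_matrix)
  Tt <- nrow(S); Nc <- ncol(S)
  h <- as.integer(h)
  if (Tt < h + Nc * h + 2L) stop("series too short for order ", h, " with ", Nc, " nodes")
  clip <- 1 - 1e-6
  if (any(abs(S) >= 1)) {
    S <- pmin(pmax(S, -clip), clip)
    message("states at |1| clipped before artanh")
  }
  # design rows: t = h .. T-1 predict S(t+1); lag blocks most recent first
  rows <- h:(Tt - 1L)
  Z <- do.call(cbind, lapply(seq_len(h), function(l) S[rows - l + 1L, , drop = FALSE]))
  Z <- cbind(Z, 1)
  Y <- atanh(S[rows + 1L, , drop = FALSE])
  p <- ncol(Z)
  pen <- diag(ridge, p); pen[p, p] <- 0    # intercept unpenalised
  coef <- solve(crossprod(Z) + pen, crossprod(Z, Y))
  W <- array(0, c(Nc, Nc, h))
  for (l in seq_len(h))
    W[, , l] <- t(coef[((l - 1L) * Nc + 1L):(l * Nc), , drop = FALSE])
  bias <- as.numeric(coef[p, ])
  model <- hfcm(W, bias)
  pred <- tanh(Z %*% coef)
  model$rmse <- sqrt(mean((pred - S[rows + 1L, ])^2))
  model
}

#' Simulate an HFCM forward
#'
#' Generates `steps` states from an initial history by iterating
#' [hfcm_predict()]. Used for parameter-recovery checks.
#'
#' @param model An [hfcm()].
#' @param init Matrix `Nc x h` initial history, most recent first.
#' @param steps Number of steps.
#' @return Matrix `(h + steps) x Nc`, oldest state first.
#' @export
hfcm_simulate <- function(model, init, steps) {
  h <- model$order
  Nc <- model$n_nodes
  out <- matrix(0, h + steps, Nc)
  out[seq_len(h), ] <- t(init[, h:1, drop = FALSE])   # oldest first
  for (s in seq_len(steps)) {
    t_now <- h + s - 1L
    hist <- t(out[t_now:(t_now - h + 1L), , drop = FALSE])
    out[h + s, ] <- hfcm_predict(model, hist)
  }
  out
}
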