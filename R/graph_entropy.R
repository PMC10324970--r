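#' Granger causality test between two series
#'
#' Tests whether past values of `x` improve prediction of `y` beyond `y`'s own
#' past. A restricted OLS regresses `y` on its own lags; an unrestricted OLS
#' adds the same number of lags of `x`. The F statistic
#' `F = ((SSR_r - SSR_u)/L) / (SSR_u/(n - 2L - 1))` is referred to the
#' `F(L, n - 2L - 1)` distribution. The lag order `L` is selected by BIC on
#' the restricted autoregression of `y` over `1..max_lag`, so the choice of
#' lag does not depend on the candidate cause and the test keeps its nominal
#' size.
#'
#' @param x Candidate cause series.
#' @param y Target series (same length as `x`, length >= 10*max_lag).
#' @param max_lag Largest lag order considered (default 8).
#' @param alpha Significance level for the binary causality call (default 0.05).
#' @return A `granger_causal` list: `prob` (p-value), `C` (1 if
#'   `prob < alpha`, else 0), `lag` (selected order), `F` (statistic).
#' @export
granger_causal <- function(x, y, max_lag = 8L, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(y)
  if (length(x) != n) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("series must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: constant series")
  max_lag <- as.integer(max_lag)
  if (n < 10L * max_lag) max_lag <- max(1L, n %/% 10L)
  lag <- select_ar_order_bic(y, max_lag)
  # common estimation sample: drop first `lag` observations
  yt <- y[(lag + 1L):n]
  n_eff <- length(yt)
  Yl <- stats::embed(y, lag + 1L)[, -1L, drop = FALSE]
  Xl <- stats::embed(x, lag + 1L)[, -1L, drop = FALSE]
  Zr <- cbind(1, Yl)
  Zu <- cbind(1, Yl, Xl)
  ssr_r <- ols_ssr(Zr, yt)
  ssr_u <- ols_ssr(Zu, yt)
  df2 <- n_eff - 2L * lag - 1L
  if (df2 <= 0) stop("series too short for selected lag")
  Fstat <- ((ssr_r - ssr_u) / lag) / (ssr_u / df2)
  if (!is.finite(Fstat)) stop("singular design matrix in Granger regression")
  prob <- stats::pf(Fstat, lag, df2, lower.tail = FALSE)
  structure(list(prob = prob, C = as.integer(prob < alpha), lag = lag, F = Fstat),
            class = "granger_causal")
}

ols_ssr <- function(Z, y) {
  fit <- stats::.lm.fit(Z, y)
  sum(fit$residuals^2)
}

select_ar_order_bic <- function(y, max_lag) {
  n <- length(y)
  bic <- numeric(max_lag)
  for (L in seq_len(max_lag)) {
    yt <- y[(L + 1L):n]
    Z <- cbind(1, stats::embed(y, L + 1L)[, -1L, drop = FALSE])
    ssr <- ols_ssr(Z, yt)
    m <- length(yt)
    bic[L] <- m * log(max(ssr / m, 1e-300)) + (L + 1L) * log(m)
  }
  which.min(bic)
}

#' Spurious correlation coefficient
#'
#' Edge weight for the causality graph: 1 when there is no causality
#' (`C = 0`); otherwise `C - |PCC| = 1 - |PCC|`. A strongly correlated but
#' causal pair gets a small weight; an uncorrelated-or-noncausal pair gets a
#' weight near 1. The result always lies in `[0, 1]`.
#'
#' @param cres A [granger_causal()] result (or anything with a `C` field).
#' @param pcc Pearson correlation coefficient in `[-1, 1]`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
spurious_coefficient <- function(cres, pcc) {
  if (abs(pcc) > 1 + 1e-12) stop("|pcc| must be <= 1")
  pcc <- max(-1, min(1, pcc))
  if (cres$C == 0L) 1 else 1 - abs(pcc)
}

#' Build the dynamic causality graph of a trial
#'
#' The trial is split into time intervals by a window plan. In each interval
#' every ordered channel pair is Granger-tested and the spurious correlation
#' coefficient computed from the same windowed segments; the undirected edge
#' weight is the mean (or min) of the two directed coefficients, or both
#' directions are kept (`edge_mode = "directed"`, asymmetric matrix).
#' Signals are decimated (anti-aliased) to `decimate_to` Hz before fitting to
#' keep the OLS well conditioned on short windows.
#'
#' @param trial A [trial()].
#' @param plan A [plan_windows()] plan at the analysis rate; default gives
#'   non-overlapping windows of a quarter second.
#' @param max_lag,alpha Passed to [granger_causal()].
#' @param edge_mode `"mean"`, `"min"` or `"directed"`.
#' @param decimate_to Analysis rate in Hz (default 1000; no-op if the trial is
#'   already at or below it).
#' @return A `dynamic_graph`: list with `graphs` (list of `n_channels^2`
#'   weight matrices, zero diagonal) and `plan`.
#' @export
build_dynamic_graph <- function(trial, plan = NULL, max_lag = 8L, alpha = 0.05,
                                edge_mode = c("mean", "min", "directed"),
                                decimate_to = 1000) {
  stopifnot(inherits(trial, "semg_trial"))
  edge_mode <- match.arg(edge_mode)
  X <- trial$samples
  fs <- trial$fs
  if (fs > decimate_to) {
    X <- decimate_matrix(X, fs, decimate_to)
    fs <- decimate_to
  }
  if (is.null(plan)) plan <- plan_windows(nrow(X), max(2L, round(fs / 4)))
  ch <- ncol(X)
  graphs <- vector("list", plan$T)
  for (t in seq_len(plan$T)) {
    Wm <- window_slice(X, plan, t)
    R <- matrix(0, ch, ch)
    for (i in seq_len(ch - 1L)) {
      for (j in (i + 1L):ch) {
        res <- tryCatch({
          pcc <- stats::cor(Wm[, i], Wm[, j])
          gij <- granger_causal(Wm[, i], Wm[, j], max_lag, alpha)
          gji <- granger_causal(Wm[, j], Wm[, i], max_lag, alpha)
          c(spurious_coefficient(gij, pcc), spurious_coefficient(gji, pcc))
        }, error = function(e) stop("interval ", t, ", channels (", i, ",", j, "): ",
                                    conditionMessage(e)))
        if (edge_mode == "directed") {
          R[i, j] <- res[1L]; R[j, i] <- res[2L]
        } else {
          w <- if (edge_mode == "mean") mean(res) else min(res)
          R[i, j] <- w; R[j, i] <- w
        }
      }
    }
    graphs[[t]] <- R
  }
  structure(list(graphs = graphs, plan = plan, edge_mode = edge_mode),
            class = "dynamic_graph")
}

decimate_matrix <- function(X, fs, fs_out) {
  q <- max(1L, floor(fs / fs_out))
  if (q == 1L) return(X)
  lp <- signal::butter(8, 0.8 / q, type = "low")
  idx <- seq(1L, nrow(X), by = q)
  apply(X, 2L, function(x) signal::filtfilt(lp, x)[idx])
}

#' Vertex entropy of a weighted graph
#'
#' `e(v_i) = -sum_{j != i} R_ij * log(R_ij)` over incident edge weights, in
#' nats, with the limit convention `0 * log 0 = 0`. Weights must lie in
#' `[0, 1]`, so each term and the sum are non-negative.
#'
#' @param R Symmetric-role weight matrix with zero diagonal, entries in `[0,1]`.
#' @param i Vertex index (1-based).
#' @return Non-negative scalar.
#' @export
vertex_entropy <- function(R, i) {
  w <- R[i, -i]
  w <- w[w > 0]
  if (length(w) == 0L) return(0)
  -sum(w * log(w))
}

#' Graph entropy
#'
#' Sum of [vertex_entropy()] over all vertices.
#'
#' @param R Weight matrix as in [vertex_entropy()].
#' @return Non-negative scalar.
#' @export
graph_entropy <- function(R) {
  sum(vapply(seq_len(nrow(R)), function(i) vertex_entropy(R, i), numeric(1)))
}

#' Entropy feature vector of a dynamic graph
#'
#' Concatenates the per-interval graph entropies (length `T`) with the
#' per-interval, per-vertex entropies (length `T * n_channels`), giving a
#' fixed-length vector of `T * (1 + n_channels)` features.
#'
#' @param dg A [build_dynamic_graph()] result.
#' @return Named numeric vector.
#' @export
entropy_features <- function(dg) {
  stopifnot(inherits(dg, "dynamic_graph"))
  Tn <- length(dg$graphs)
  ch <- nrow(dg$graphs[[1L]])
  eg <- vapply(dg$graphs, graph_entropy, numeric(1))
  ev <- t(vapply(dg$graphs, function(R)
    vapply(seq_len(ch), function(i) vertex_entropy(R, i), numeric(1)),
    numeric(ch)))
  out <- c(eg, as.numeric(ev))
  names(out) <- c(paste0("eG_t", seq_len(Tn)),
                  as.vector(outer(seq_len(Tn), seq_len(ch),
                                  function(t, i) paste0("eV_t", t, "_ch", i))))
  out
}

#' Strategy-1 features for a whole trialset
#'
#' Runs [build_dynamic_graph()] + [entropy_features()] per trial. With
#' `include = "weights"` the raw flattened edge weights are used instead
#' (the graph-only variant); `"both"` concatenates the two blocks.
#'
#' @param ts A [trialset()].
#' @param include `"entropy"`, `"weights"` or `"both"`.
#' @param ... Passed to [build_dynamic_graph()].
#' @return A [feature_matrix()].
#' @export
graph_entropy_features <- function(ts, include = c("entropy", "weights", "both"), ...) {
  include <- match.arg(include)
  rows <- lapply(ts$trials, function(tr) {
    dg <- build_dynamic_graph(tr, ...)
    ef <- entropy_features(dg)
    if (include == "entropy") return(ef)
    ch <- nrow(dg$graphs[[1L]])
    ut <- upper.tri(dg$graphs[[1L]])
    wf <- unlist(lapply(dg$graphs, function(R) R[ut]))
    names(wf) <- paste0("w", seq_along(wf))
    if (include == "weights") wf else c(ef, wf)
  })
  feature_matrix(do.call(rbind, rows), trial_labels(ts))
}
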