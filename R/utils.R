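# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream. `seed = NULL` uses the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Centered moving average with replicated ends; span forced odd.
moving_average <- function(x, span) {
  span <- max(1L, as.integer(span))
  if (span %% 2L == 0L) span <- span + 1L
  if (span == 1L || length(x) < 2L) return(x)
  half <- (span - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / span, span), sides = 2L))[(half + 1L):(half + length(x))]
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# One-hot target matrix for 0-based integer labels.
one_hot <- function(y, n_classes) {
  stopifnot(all(y >= 0L), all(y < n_classes))
  T <- matrix(0, length(y), n_classes)
  T[cbind(seq_along(y), y + 1L)] <- 1
  T
}

logistic <- function(x) 1 / (1 + exp(-x))

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) return(0)
  mean(x^4) / s2^2 - 3
}

# Stratified fold assignment: returns integer fold id per observation.
stratified_folds <- function(y, folds, seed = NULL) {
  with_seed(seed, {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
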