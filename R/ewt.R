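#' Nearest-neighbour end padding of a series
#'
#' Extends both ends of `x` by `pad` samples using nearest-neighbour
#' forecasting: each appended sample is the mean successor of the `k` most
#' similar length-`k` windows found in the original series. Used to suppress
#' boundary effects before the empirical wavelet transform. The interior of
#' the output equals `x` exactly.
#'
#' @param x Numeric series, longer than `k`.
#' @param pad Samples to append at each end (0 = identity).
#' @param k Window length and neighbour count.
#' @return Numeric vector of length `length(x) + 2 * pad`.
#' @export
knn_pad <- function(x, pad, k = 16L) {
  n <- length(x)
  pad <- as.integer(pad); k <- as.integer(k)
  if (k < 1L || n <= k) stop("need length(x) > k >= 1")
  if (pad < 0L) stop("pad must be >= 0")
  if (pad > n) stop("pad must not exceed length(x)")
  if (pad == 0L) return(x)
  right <- knn_forecast(x, pad, k)
  left <- rev(knn_forecast(rev(x), pad, k))
  c(left, x, right)
}

# Iterated one-step NN forecast beyond the right end of x.
knn_forecast <- function(x, steps, k) {
  n <- length(x)
  # candidate windows in x with a successor: starts 1..(n-k)
  starts <- seq_len(n - k)
  wins <- t(vapply(starts, function(s) x[s:(s + k - 1L)], numeric(k)))
  succ <- x[starts + k]
  ext <- x
  out <- numeric(steps)
  for (s in seq_len(steps)) {
    q <- ext[(length(ext) - k + 1L):length(ext)]
    d2 <- rowSums(sweep(wins, 2L, q)^2)
    nn <- order(d2)[seq_len(min(k, length(d2)))]
    out[s] <- mean(succ[nn])
    ext <- c(ext, out[s])
  }
  out
}

#' Detect empirical wavelet band boundaries
#'
#' Computes the FFT magnitude spectrum, smooths it, and places boundaries at
#' the frequencies of the local minima that separate the dominant spectral
#' modes. With integer `n_bands`, the `n_bands - 1` minima separating the
#' `n_bands` largest modes are returned; with `"auto"`, modes whose peak
#' exceeds `peak_frac` of the spectrum maximum define the segmentation.
#'
#' @param x Numeric series (length >= 64).
#' @param fs Sampling rate in Hz.
#' @param n_bands Integer number of bands, or `"auto"`.
#' @param smooth_span Moving-average span for the spectrum (default
#'   `length/64`, forced odd).
#' @param peak_frac Relative peak threshold for `"auto"` (default 0.1).
#' @return Increasing vector of boundary frequencies in Hz (possibly empty).
#' @export
ewt_boundaries <- function(x, fs, n_bands = "auto", smooth_span = NULL,
                           peak_frac = 0.1) {
  n <- length(x)
  if (n < 64L) stop("need length(x) >= 64")
  X <- abs(stats::fft(x))[seq_len(n %/% 2L + 1L)]
  freq <- (seq_along(X) - 1L) * fs / n
  span <- smooth_span %||% max(3L, n %/% 64L)
  Xs <- moving_average(X, span)
  n_half <- length(Xs)
  # modes by peak picking with neighbourhood suppression (robust against the
  # plateaus a boxcar smoother makes out of narrow spectral lines)
  pick_peaks <- function(k_max, min_height) {
    tmp <- Xs
    peaks <- integer(0)
    while (length(peaks) < k_max) {
      j <- which.max(tmp)
      if (!is.finite(tmp[j]) || tmp[j] < min_height) break
      peaks <- c(peaks, j)
      lo <- max(1L, j - 2L * span); hi <- min(n_half, j + 2L * span)
      tmp[lo:hi] <- -Inf
    }
    sort(peaks)
  }
  valley <- function(lo, hi) {
    # deepest point between two peaks; near-ties resolved toward the midpoint
    seg <- lo:hi
    v <- Xs[seg]
    tol <- 1e-6 * (max(v) - min(v))
    cand <- seg[v <= min(v) + tol + 1e-300]
    cand[which.min(abs(cand - (lo + hi) / 2))]
  }
  if (identical(n_bands, "auto")) {
    big <- pick_peaks(n_half, peak_frac * max(Xs))
    if (length(big) <= 1L) return(numeric(0))
  } else {
    n_bands <- as.integer(n_bands)
    if (n_bands <= 1L) return(numeric(0))
    big <- pick_peaks(n_bands, 0)
    if (length(big) < n_bands)
      stop("spectrum has only ", length(big), " modes; request fewer bands")
  }
  bounds <- vapply(seq_len(length(big) - 1L), function(i)
    valley(big[i], big[i + 1L]), numeric(1))
  sort(freq[bounds])
}

# Meyer transition polynomial on [0,1].
meyer_beta <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

#' Build an empirical wavelet filter bank
#'
#' Meyer-type construction on the FFT grid of length `n`: a scaling function
#' supported on `[0, w1]`, band-pass wavelets between consecutive boundaries,
#' and a final high-pass wavelet up to Nyquist. Transition half-widths are
#' `gamma * w`. The bank is a tight frame: the squared filter magnitudes sum
#' to 1 at every grid frequency.
#'
#' @param n Signal length (grid size).
#' @param fs Sampling rate in Hz.
#' @param boundaries Increasing boundary frequencies in `(0, fs/2)` (possibly
#'   empty, giving a single all-pass band).
#' @param gamma Transition ratio in `(0, 1)`; must satisfy
#'   `gamma < min (w[i+1]-w[i]) / (w[i+1]+w[i])` over consecutive boundaries
#'   (and the analogous conditions at 0 and Nyquist) so transitions do not
#'   overlap.
#' @return An `ewt_bank`: list with `filters` (an `n x (K+1)` matrix of
#'   real frequency responses over the full FFT grid), `boundaries`, `gamma`.
#' @export
ewt_filter_bank <- function(n, fs, boundaries, gamma = 0.2) {
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0,1)")
  w <- 2 * pi * boundaries / fs            # normalised to [0, pi]
  if (length(w) > 0) {
    if (is.unsorted(w, strictly = TRUE) || any(w <= 0) || any(w >= pi))
      stop("boundaries must be strictly increasing inside (0, fs/2)")
    ww <- c(w, pi)
    for (i in seq_len(length(ww) - 1L)) {
      lim <- (ww[i + 1L] - ww[i]) / (ww[i + 1L] + ww[i])
      if (gamma >= lim)
        stop(sprintf("gamma %.3f violates admissibility %.3f between boundaries %d and %d",
                     gamma, lim, i, i + 1L))
    }
  }
  omega <- 2 * pi * (0:(n - 1L)) / n
  omega <- pmin(omega, 2 * pi - omega)     # symmetric |frequency| in [0, pi]
  K <- length(w)
  filters <- matrix(0, n, K + 1L)
  trans <- function(om, wn) {
    # rising edge around wn over [(1-gamma) wn, (1+gamma) wn]
    meyer_beta((om - (1 - gamma) * wn) / (2 * gamma * wn))
  }
  if (K == 0L) {
    filters[, 1L] <- 1
  } else {
    # scaling function on [0, w1]
    filters[, 1L] <- cos(pi / 2 * trans(omega, w[1L]))
    filters[omega <= (1 - gamma) * w[1L], 1L] <- 1
    filters[omega >= (1 + gamma) * w[1L], 1L] <- 0
    for (b in seq_len(K)) {
      lo <- w[b]
      hi <- if (b < K) w[b + 1L] else Inf
      f <- numeric(n)
      ris <- sin(pi / 2 * trans(omega, lo))
      f[omega >= (1 + gamma) * lo] <- 1
      sel <- omega > (1 - gamma) * lo & omega < (1 + gamma) * lo
      f[sel] <- ris[sel]
      if (is.finite(hi)) {
        fall <- cos(pi / 2 * trans(omega, hi))
        sel2 <- omega > (1 - gamma) * hi & omega < (1 + gamma) * hi
        f[sel2] <- f[sel2] * fall[sel2]
        f[omega >= (1 + gamma) * hi] <- 0
      }
      filters[, b + 1L] <- f
    }
  }
  structure(list(filters = filters, boundaries = boundaries, gamma = gamma,
                 n = n, fs = fs),
            class = "ewt_bank")
}

#' Empirical wavelet decomposition
#'
#' Decomposes `x` with a Meyer-type tight-frame filter bank over the given
#' boundaries. The returned `components` are the synthesis subbands (spectrum
#' multiplied by the squared filter response), which sum to `x` exactly
#' because the squared responses partition unity. The analysis coefficients
#' (spectrum times the filter response, satisfying Parseval exactly) are
#' available via [ewt_coefficients()].
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param boundaries Boundary frequencies (see [ewt_boundaries()]).
#' @param gamma Transition ratio (default 0.2).
#' @return A list with `decomposition` (class `decomposition_result`:
#'   `components` matrix `n x (K+1)`, `method = "EWT"`, zero `residual`) and
#'   `bank` (the [ewt_filter_bank()]).
#' @export
ewt_decompose <- function(x, fs, boundaries, gamma = 0.2) {
  n <- length(x)
  bank <- ewt_filter_bank(n, fs, boundaries, gamma)
  X <- stats::fft(x)
  comp <- apply(bank$filters, 2L, function(f) Re(stats::fft(X * f^2, inverse = TRUE) / n))
  comp <- matrix(comp, n)
  colnames(comp) <- paste0("band", seq_len(ncol(comp)))
  dec <- structure(list(components = comp, method = "EWT",
                        residual = numeric(n)),
                   class = "decomposition_result")
  list(decomposition = dec, bank = bank)
}

#' Analysis coefficients of an EWT bank
#'
#' Single-filtered subband series `c_b = ifft(fft(x) * filter_b)`. Because
#' the squared filter responses sum to one, the subband energies sum exactly
#' to the signal energy (Parseval for the tight frame).
#'
#' @param x Numeric series whose length matches the bank.
#' @param bank An [ewt_filter_bank()].
#' @return Matrix `n x (K+1)` of coefficient series.
#' @export
ewt_coefficients <- function(x, bank) {
  stopifnot(inherits(bank, "ewt_bank"), length(x) == bank$n)
  X <- stats::fft(x)
  out <- apply(bank$filters, 2L, function(f) Re(stats::fft(X * f, inverse = TRUE) / bank$n))
  matrix(out, bank$n)
}

#' Differential entropy of a series (Gaussian estimator)
#'
#' `h = 0.5 * ln(2 pi e sigma^2)` in nats with the plug-in variance
#' `sigma^2 = mean((x - mean(x))^2)`. Equivalently
#' `0.5 ln(E/N) + 0.5 ln(2 pi e)` where `E` is the centred signal energy.
#' Doubling the amplitude raises the entropy by exactly `ln 2`.
#'
#' @param x Numeric series, length >= 2, non-constant.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  s2 <- mean((x - mean(x))^2)
  if (s2 <= 0) stop("degenerate input: constant series has sigma^2 = 0")
  0.5 * log(2 * pi * exp(1) * s2)
}
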