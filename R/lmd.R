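#' Local mean decomposition
#'
#' Iteratively separates a signal into product functions (PFs), each the
#' elementwise product of a slowly varying envelope and a pure
#' frequency-modulated series in `[-1, 1]`, plus a residual. Per PF the
#' sifting loop computes local extrema, the piecewise local mean
#' `m = (n_k + n_{k+1})/2` and local magnitude `a = |n_k - n_{k+1}|/2`
#' (both held between extrema and smoothed by a moving average), subtracts
#' the mean, divides by the magnitude, and repeats until the magnitude
#' estimate is within `sift_tol` of 1. The PF is subtracted and extraction
#' continues until the residual has fewer than 3 extrema or `max_pf` is
#' reached. The sum of PFs plus residual reproduces the input exactly (it is
#' a subtractive identity).
#'
#' @param x Numeric series (length >= 32).
#' @param max_pf Maximum number of product functions (default 8).
#' @param smooth_span Moving-average span in samples (odd; default 11).
#' @param sift_tol Stop sifting when `max|a - 1| < sift_tol` (default 1e-2).
#' @param max_sift Sifting iteration cap per PF (default 30; hitting it
#'   accepts the current iterate with a warning).
#' @param pad_frac Mirror-extension fraction per end used to contain the end
#'   effect (default 0.1); the extension is trimmed from all outputs.
#' @return An `lmd_result`: list with `pfs` (list of `product_function`
#'   objects with fields `pf`, `envelope`, `fm`) and `residual`.
#' @export
lmd_decompose <- function(x, max_pf = 8L, smooth_span = 11L, sift_tol = 1e-2,
                          max_sift = 30L, pad_frac = 0.1) {
  x <- as.numeric(x)
  if (length(x) < 32L) stop("need length(x) >= 32")
  # mirror-extend to contain the end effect (extrema extrapolation at the
  # series ends otherwise compounds across sifting iterations); everything
  # is trimmed back, so the subtractive identity holds on the interior
  n0 <- length(x)
  pad <- min(n0 - 1L, max(0L, round(pad_frac * n0)))
  if (pad > 0L) x <- c(x[(pad + 1L):2L], x, x[(n0 - 1L):(n0 - pad)])
  keep <- (pad + 1L):(pad + n0)
  res <- x
  x_scale <- stats::sd(x)
  pfs <- list()
  for (p in seq_len(max_pf)) {
    if (x_scale > 0 && stats::sd(res) < 1e-8 * x_scale) break
    ext <- local_extrema(res)
    if (length(ext) < 3L) break
    s <- res
    env_total <- rep(1, length(x))
    ok <- FALSE
    prev_crit <- Inf
    for (it in seq_len(max_sift)) {
      ee <- local_extrema(s)
      if (length(ee) < 3L) { ok <- TRUE; break }
      ma <- local_mean_mag(s, ee, smooth_span)
      h <- s - ma$m
      # floor the magnitude: near-equal adjacent extrema would otherwise
      # drive h/a to enormous values on flat stretches
      a <- pmax(ma$a, 1e-2 * stats::median(ma$a) + 1e-300)
      s_new <- h / a
      env_total <- env_total * a
      s <- s_new
      ee2 <- local_extrema(s)
      if (length(ee2) < 3L) { ok <- TRUE; break }
      a_chk <- local_mean_mag(s, ee2, smooth_span)$a
      crit <- max(abs(a_chk - 1))
      if (crit < sift_tol) { ok <- TRUE; break }
      # broadband signals never reach the max-norm tolerance; accept the
      # iterate once the criterion stops improving
      if (crit > 0.95 * prev_crit) { ok <- TRUE; break }
      prev_crit <- crit
    }
    if (!ok) warning("PF ", p, ": sifting did not converge in ", max_sift,
                     " iterations; accepting current iterate")
    # fold any residual amplitude of s into the envelope so the FM part lies
    # in [-1, 1] exactly without clipping (pf = envelope * fm stays exact)
    cmax <- max(abs(s), 1)
    fm <- s / cmax
    env_total <- env_total * cmax
    pf <- env_total * fm
    pfs[[p]] <- structure(list(pf = pf[keep], envelope = env_total[keep],
                               fm = fm[keep]),
                          class = "product_function")
    res <- res - pf
  }
  structure(list(pfs = pfs, residual = res[keep], method = "LMD"),
            class = "lmd_result")
}

# Indices of interior local extrema (maxima and minima), plateau-safe.
local_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  turn <- which(s[-1L] != s[-length(s)])
  nz[turn] + 1L
}

# Piecewise local mean and magnitude from successive extrema, held between
# extrema (step interpolation at midpoints) then smoothed.
local_mean_mag <- function(x, ext, span) {
  n <- length(x)
  vals <- x[ext]
  mids <- (vals[-length(vals)] + vals[-1L]) / 2
  mags <- abs(vals[-length(vals)] - vals[-1L]) / 2
  m <- numeric(n); a <- numeric(n)
  # segment k spans ext[k] .. ext[k+1]
  m[seq_len(ext[1L])] <- mids[1L]; a[seq_len(ext[1L])] <- mags[1L]
  for (k in seq_along(mids)) {
    idx <- ext[k]:ext[k + 1L]
    m[idx] <- mids[k]; a[idx] <- mags[k]
  }
  last <- ext[length(ext)]
  if (last < n) {
    m[(last + 1L):n] <- mids[length(mids)]
    a[(last + 1L):n] <- mags[length(mags)]
  }
  list(m = moving_average(m, span), a = moving_average(a, span))
}

#' @export
print.lmd_result <- function(x, ...) {
  cat(sprintf("<lmd_result> %d product functions + residual (n = %d)\n",
              length(x$pfs), length(x$residual)))
  invisible(x)
}

#' Instantaneous frequency of an FM series
#'
#' Phase derivative of the analytic signal, in Hz; edges are unreliable and
#' should be trimmed by the caller.
#'
#' @param fm Numeric FM series.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `length(fm) - 1`.
#' @export
instantaneous_frequency <- function(fm, fs) {
  z <- analytic_signal(fm)
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi       # unwrap steps into (-pi, pi]
  dph * fs / (2 * pi)
}

#' LMD feature vector of a trial
#'
#' Per channel, per retained product function: energy (mean square), mean and
#' SD of the instantaneous amplitude (envelope), and mean and SD of the
#' instantaneous frequency (from the analytic phase of the FM part, edges
#' trimmed 5%). Missing PFs are zero-padded so the vector length is fixed at
#' `n_channels * n_pf * 5`.
#'
#' @param trial A [trial()].
#' @param n_pf Number of PFs retained per channel (default 4).
#' @param ... Passed to [lmd_decompose()].
#' @return Named numeric vector.
#' @export
lmd_features <- function(trial, n_pf = 4L, ...) {
  stopifnot(inherits(trial, "semg_trial"))
  X <- trial$samples
  fs <- trial$fs
  out <- numeric(0)
  args <- list(...)
  if (is.null(args$max_pf)) args$max_pf <- n_pf
  for (ch in seq_len(ncol(X))) {
    dec <- do.call(lmd_decompose, c(list(X[, ch]), args))
    feats <- matrix(0, 5L, n_pf)
    for (p in seq_len(min(n_pf, length(dec$pfs)))) {
      pf <- dec$pfs[[p]]
      n <- length(pf$pf)
      trim <- max(1L, round(0.05 * n))
      keep <- trim:(n - trim)
      fi <- instantaneous_frequency(pf$fm, fs)
      fi <- fi[keep[keep <= length(fi)]]
      fi <- pmin(pmax(fi, 0), fs / 2)
      feats[, p] <- c(mean(pf$pf^2),
                      mean(pf$envelope[keep]), stats::sd(pf$envelope[keep]),
                      mean(fi), stats::sd(fi))
    }
    out <- c(out, as.numeric(feats))
  }
  names(out) <- paste0("ch", rep(seq_len(ncol(X)), each = 5L * n_pf),
                       "_pf", rep(rep(seq_len(n_pf), each = 5L), ncol(X)),
                       "_", rep(c("energy", "amp_mean", "amp_sd", "if_mean", "if_sd"),
                                n_pf * ncol(X)))
  out
}

#' Strategy-4 LMD features for a trialset
#'
#' @param ts A [trialset()].
#' @param n_pf PFs retained per channel.
#' @param ... Passed to [lmd_decompose()].
#' @return A [feature_matrix()].
#' @export
lmd_feature_matrix <- function(ts, n_pf = 4L, ...) {
  rows <- lapply(ts$trials, lmd_features, n_pf = n_pf, ...)
  feature_matrix(do.call(rbind, rows), trial_labels(ts))
}
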