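# Strategy 3 composite: EWT band decomposition -> windowed differential
# entropy series -> per-channel HFCM over the band DE series, assembled into
# a fixed-length feature vector per trial.

# Differential entropy over sliding windows of a series.
windowed_de <- function(x, plan) {
  vapply(seq_len(plan$T), function(t) {
    w <- x[(plan$starts[t] + 1L):(plan$starts[t] + plan$window_length)]
    s2 <- mean((w - mean(w))^2)
    0.5 * log(2 * pi * exp(1) * max(s2, 1e-300))
  }, numeric(1))
}

# Min-max rescale to [-0.9, 0.9]; constant input maps to 0.
rescale_squash <- function(x, lim = 0.9) {
  r <- range(x)
  if (r[2L] - r[1L] < 1e-12) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L]) * 2 * lim - lim
}

# Admissible fallback boundaries: geometric spacing inside the EMG band,
# capped below Nyquist so gamma transitions fit.
default_boundaries <- function(fs, n_bands, gamma) {
  if (n_bands <= 1L) return(numeric(0))
  f_hi <- min(450, 0.95 * (fs / 2) * (1 - gamma) / (1 + gamma))
  f_lo <- max(20, f_hi / 2^(n_bands - 1L))
  exp(seq(log(f_lo), log(f_hi), length.out = n_bands - 1L))
}

#' Strategy-3 feature vector of a single trial
#'
#' Per channel: nearest-neighbour padding ([knn_pad()]), empirical wavelet
#' decomposition into `n_bands` ([ewt_decompose()]; boundaries detected from
#' the spectrum, falling back to fixed geometric spacing if detection or
#' admissibility fails), windowed differential entropy per band, rescaling of
#' the DE series into `(-1, 1)`, and an order-`h` HFCM fitted over the band
#' DE series ([hfcm_fit()], nodes = bands). The feature vector concatenates
#' the HFCM weights and biases with the mean and SD of the raw DE per band:
#' `n_channels * (n_bands^2 * h + n_bands + 2 * n_bands)` values.
#'
#' @param trial A [trial()].
#' @param n_bands Number of EWT bands (default 5).
#' @param gamma Transition ratio (default 0.2).
#' @param h HFCM order (default 2).
#' @param de_window,de_hop DE window geometry in samples; defaults give about
#'   30 windows per trial.
#' @param pad Padding samples per end before EWT (default `n/10`).
#' @param ridge HFCM ridge penalty.
#' @return Named numeric feature vector of fixed length.
#' @export
de_hfcm_ewt_features <- function(trial, n_bands = 5L, gamma = 0.2, h = 2L,
                                 de_window = NULL, de_hop = NULL,
                                 pad = NULL, ridge = 1e-3) {
  stopifnot(inherits(trial, "semg_trial"))
  X <- trial$samples
  n <- nrow(X); fs <- trial$fs
  pad <- pad %||% round(n / 10)
  de_window <- de_window %||% max(32L, round(n / 16))
  de_hop <- de_hop %||% max(1L, de_window %/% 2L)
  out <- list()
  for (ch in seq_len(ncol(X))) {
    x <- X[, ch]
    xp <- knn_pad(x, pad = pad, k = 16L)
    bands <- channel_ewt_bands(xp, fs, n_bands, gamma)
    bands <- bands[(pad + 1L):(pad + n), , drop = FALSE]   # trim padding
    plan <- plan_windows(n, de_window, de_hop)
    de_series <- apply(bands, 2L, windowed_de, plan = plan)
    states <- apply(de_series, 2L, rescale_squash)
    fit <- hfcm_fit(states, h = h, ridge = ridge)
    out[[ch]] <- c(as.numeric(fit$weights), fit$bias,
                   colMeans(de_series), apply(de_series, 2L, stats::sd))
  }
  v <- unlist(out)
  names(v) <- paste0("ch", rep(seq_len(ncol(X)), each = length(out[[1L]])),
                     "_s3f", seq_len(length(out[[1L]])))
  v
}

# EWT into exactly n_bands components, adaptive boundaries with fallback.
channel_ewt_bands <- function(x, fs, n_bands, gamma) {
  b <- tryCatch(ewt_boundaries(x, fs, n_bands), error = function(e) NULL)
  dec <- NULL
  if (!is.null(b) && length(b) == n_bands - 1L)
    dec <- tryCatch(ewt_decompose(x, fs, b, gamma), error = function(e) NULL)
  if (is.null(dec))
    dec <- ewt_decompose(x, fs, default_boundaries(fs, n_bands, gamma), gamma)
  dec$decomposition$components
}

#' Strategy-3 features for a trialset, with ablations
#'
#' `ablation` selects which of the three ingredients contribute:
#' `"de"` windowed differential entropy on raw channels (mean/SD);
#' `"fcm"` HFCM across channels fitted on windowed RMS series;
#' `"ewt"` band RMS summaries; `"de-fcm"` HFCM over per-channel DE series
#' plus DE summaries; `"de-ewt"` band-wise DE summaries; `"fcm-ewt"` HFCM
#' over band RMS series; `"de-fcm-ewt"` the full pipeline
#' ([de_hfcm_ewt_features()]).
#'
#' @param ts A [trialset()].
#' @param ablation One of the seven variants above (default full).
#' @param ... Passed to [de_hfcm_ewt_features()] / the shared stages.
#' @return A [feature_matrix()].
#' @export
strategy3_features <- function(ts,
                               ablation = c("de-fcm-ewt", "de", "fcm", "ewt",
                                            "de-fcm", "de-ewt", "fcm-ewt"),
                               n_bands = 5L, gamma = 0.2, h = 2L, ...) {
  ablation <- match.arg(ablation)
  rows <- lapply(ts$trials, function(tr)
    strategy3_trial_row(tr, ablation, n_bands, gamma, h, ...))
  feature_matrix(do.call(rbind, rows), trial_labels(ts))
}

strategy3_trial_row <- function(tr, ablation, n_bands, gamma, h, ...) {
  X <- tr$samples
  n <- nrow(X); fs <- tr$fs
  w <- max(32L, round(n / 16)); hp <- max(1L, w %/% 2L)
  plan <- plan_windows(n, w, hp)
  if (ablation == "de-fcm-ewt")
    return(de_hfcm_ewt_features(tr, n_bands = n_bands, gamma = gamma, h = h, ...))
  if (ablation == "de") {
    de <- apply(X, 2L, windowed_de, plan = plan)
    return(c(colMeans(de), apply(de, 2L, stats::sd)))
  }
  if (ablation == "fcm") {
    rms <- apply(X, 2L, function(x) vapply(seq_len(plan$T), function(t)
      sqrt(mean(window_slice(cbind(x), plan, t)^2)), numeric(1)))
    fit <- hfcm_fit(apply(rms, 2L, rescale_squash), h = h)
    return(c(as.numeric(fit$weights), fit$bias))
  }
  if (ablation == "de-fcm") {
    de <- apply(X, 2L, windowed_de, plan = plan)
    fit <- hfcm_fit(apply(de, 2L, rescale_squash), h = h)
    return(c(as.numeric(fit$weights), fit$bias, colMeans(de),
             apply(de, 2L, stats::sd)))
  }
  # remaining variants need the band decomposition
  per_ch <- lapply(seq_len(ncol(X)), function(ch) {
    bands <- channel_ewt_bands(X[, ch], fs, n_bands, gamma)
    if (ablation == "ewt") {
      rms <- apply(bands, 2L, function(b) vapply(seq_len(plan$T), function(t)
        sqrt(mean(window_slice(cbind(b), plan, t)^2)), numeric(1)))
      c(colMeans(rms), apply(rms, 2L, stats::sd))
    } else if (ablation == "de-ewt") {
      de <- apply(bands, 2L, windowed_de, plan = plan)
      c(colMeans(de), apply(de, 2L, stats::sd))
    } else {                               # fcm-ewt
      rms <- apply(bands, 2L, function(b) vapply(seq_len(plan$T), function(t)
        sqrt(mean(window_slice(cbind(b), plan, t)^2)), numeric(1)))
      fit <- hfcm_fit(apply(rms, 2L, rescale_squash), h = h)
      c(as.numeric(fit$weights), fit$bias)
    }
  })
  unlist(per_ch)
}
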