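#' Configuration for the synthetic sEMG generator
#'
#' Defaults reproduce the geometry of the benchmark recordings the toolkit
#' targets: 15 finger-movement classes, 24 trials per class (360 trials in
#' total), 8 channels sampled at 4 kHz for 1 s.
#'
#' @param n_classes Number of movement classes (default 15).
#' @param trials_per_class Trials per class (default 24).
#' @param n_channels Number of sEMG channels (default 8).
#' @param fs Sampling rate in Hz (default 4000).
#' @param duration_s Trial duration in seconds (default 1).
#' @param snr_db Additive white-noise level relative to per-channel RMS
#'   (default 20 dB).
#' @param coupling_strength Lag-1 directed coupling coefficient between the
#'   class-designated channel pairs, in `[0, 1)` (default 0.6).
#' @param envelope_depth Depth of the class-specific 2-5 Hz amplitude
#'   envelope, in `[0, 1]` (default 0.6).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 15L, trials_per_class = 24L, n_channels = 8L,
                         fs = 4000, duration_s = 1.0, snr_db = 20,
                         coupling_strength = 0.6, envelope_depth = 0.6,
                         seed = 1L) {
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  if (coupling_strength < 0 || coupling_strength >= 1) stop("coupling_strength must be in [0,1)")
  if (envelope_depth < 0 || envelope_depth > 1) stop("envelope_depth must be in [0,1]")
  structure(list(n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, snr_db = snr_db,
                 coupling_strength = coupling_strength,
                 envelope_depth = envelope_depth, seed = as.integer(seed)),
            class = "synth_config")
}

# Deterministic class structure: which channels are "active" (full RMS) and
# which ordered channel pairs carry directed lag-1 coupling, per class.
class_structure <- function(cls, n_channels) {
  n_active <- max(1L, n_channels %/% 2L)
  subsets <- utils::combn(n_channels, n_active)
  active <- subsets[, (cls * 9L) %% ncol(subsets) + 1L]
  pairs <- rbind(
    c((cls %% n_channels) + 1L, ((cls + 1L) %% n_channels) + 1L),
    c(((cls + 3L) %% n_channels) + 1L, ((cls + 5L) %% n_channels) + 1L))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  list(active = unique(active), pairs = pairs)
}

#' Generate a synthetic multichannel sEMG trialset
#'
#' Each channel is an AR(2) process driven by Gaussian noise and band-pass
#' filtered to the 20-450 Hz surface-EMG band. Class identity is encoded
#' three ways: (i) a class-specific binary active-channel mask scales channel
#' RMS; (ii) class-designated ordered channel pairs receive directed lag-1
#' coupling with coefficient `coupling_strength`, creating genuine Granger
#' structure; (iii) a class-specific low-frequency (2-5 Hz) amplitude envelope
#' of depth `envelope_depth` modulates all channels. White measurement noise
#' is added at `snr_db`.
#'
#' @param cfg A [synth_config()].
#' @return A [trialset()].
#' @export
generate_semg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- round(cfg$fs * cfg$duration_s)
  bp <- semg_bandpass(cfg$fs)
  trials <- vector("list", cfg$n_classes * cfg$trials_per_class)
  k <- 0L
  with_seed(cfg$seed, {
    for (cls in seq_len(cfg$n_classes) - 1L) {
      st <- class_structure(cls, cfg$n_channels)
      f_env <- 2 + 3 * if (cfg$n_classes > 1L) cls / (cfg$n_classes - 1L) else 0
      for (r in seq_len(cfg$trials_per_class)) {
        X <- matrix(0, n, cfg$n_channels)
        for (ch in seq_len(cfg$n_channels)) {
          e <- stats::rnorm(n + 200L)
          # AR(2) resonance inside the EMG band, channel-dependent
          f0 <- 60 + 40 * ((ch - 1L) %% 4L)
          rho <- 0.95
          a1 <- 2 * rho * cos(2 * pi * f0 / cfg$fs); a2 <- -rho^2
          x <- as.numeric(stats::filter(e, c(a1, a2), method = "recursive"))
          x <- x[201L:(n + 200L)]
          x <- signal::filtfilt(bp, x)
          X[, ch] <- x / stats::sd(x)
        }
        # directed lag-1 coupling: target += beta * lagged standardized source
        if (cfg$coupling_strength > 0 && nrow(st$pairs) > 0L) {
          for (p in seq_len(nrow(st$pairs))) {
            src <- st$pairs[p, 1L]; dst <- st$pairs[p, 2L]
            lagged <- c(0, X[-n, src])
            X[, dst] <- X[, dst] + cfg$coupling_strength * lagged
            X[, dst] <- X[, dst] / stats::sd(X[, dst])
          }
        }
        # class-specific amplitude envelope, random phase per trial
        if (cfg$envelope_depth > 0) {
          tt <- (seq_len(n) - 1L) / cfg$fs
          env <- 1 + cfg$envelope_depth * sin(2 * pi * f_env * tt + stats::runif(1, 0, 2 * pi))
          X <- X * env
        }
        # active-channel mask on RMS
        mask <- rep(0.35, cfg$n_channels)
        mask[st$active] <- 1
        X <- sweep(X, 2L, mask, `*`)
        # measurement noise at snr_db, scaled by the trial-average channel
        # RMS (a common noise floor across channels); snr_db = -Inf drowns
        # the signal entirely, leaving pure noise
        if (identical(cfg$snr_db, -Inf)) {
          X <- matrix(stats::rnorm(n * cfg$n_channels), n)
        } else if (is.finite(cfg$snr_db)) {
          noise_sd <- sqrt(mean(X^2)) / 10^(cfg$snr_db / 20)
          X <- X + noise_sd * matrix(stats::rnorm(n * cfg$n_channels), n)
        }
        k <- k + 1L
        trials[[k]] <- trial(X, fs = cfg$fs, label = cls,
                             subject = sprintf("synth%02d", (r - 1L) %% 8L + 1L))
      }
    }
  })
  trialset(trials, n_classes = cfg$n_classes)
}

semg_bandpass <- function(fs) {
  hi <- min(450, 0.45 * fs)
  signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
}

#' Generate a causally coupled series pair
#'
#' `x` is white Gaussian noise; `y[t] = beta * x[t-1] + e[t]` with unit
#' variance innovations. Used as ground truth for causality testing.
#'
#' @param n Series length (>= 50).
#' @param beta Coupling coefficient; `beta = 0` gives independent series.
#' @param seed Integer seed.
#' @return A list with components `x` and `y`.
#' @export
generate_pair_causal <- function(n, beta, seed = 1L) {
  if (n < 50L) stop("n >= 50 required")
  with_seed(seed, {
    x <- stats::rnorm(n)
    e <- stats::rnorm(n)
    y <- e
    y[-1L] <- beta * x[-n] + e[-1L]
    list(x = x, y = y)
  })
}
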