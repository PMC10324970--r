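#' Construct a single sEMG trial
#'
#' A trial is one multichannel recording segment: a numeric matrix with one
#' row per sample and one column per channel, a sampling rate, and an
#' integer class label (0-based).
#'
#' @param samples Numeric matrix, `n_samples x n_channels`. All values must be
#'   finite; at least 2 samples and 1 channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Integer class index, 0-based.
#' @param subject Opaque subject identifier (default `"s1"`).
#' @return An object of class `semg_trial`.
#' @export
trial <- function(samples, fs, label = 0L, subject = "s1") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L || ncol(samples) < 1L)
    stop("trial needs >= 2 samples and >= 1 channel")
  if (!all(is.finite(samples))) stop("trial samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  label <- as.integer(label)
  if (is.na(label) || label < 0L) stop("label must be a non-negative integer")
  structure(list(samples = samples, fs = fs, label = label,
                 subject = as.character(subject)),
            class = "semg_trial")
}

#' @export
print.semg_trial <- function(x, ...) {
  cat(sprintf("<semg_trial> %d samples x %d channels @ %g Hz, label %d (subject %s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$label, x$subject))
  invisible(x)
}

#' Construct a labelled collection of sEMG trials
#'
#' All trials must share the sampling rate and channel count. Labels must lie
#' in `[0, n_classes)` and every represented class must have at least one
#' trial.
#'
#' @param trials List of [trial()] objects.
#' @param n_classes Number of classes; default `max(label) + 1`.
#' @param channel_names Optional character vector of channel names.
#' @return An object of class `semg_trialset`.
#' @export
trialset <- function(trials, n_classes = NULL, channel_names = NULL) {
  stopifnot(is.list(trials))
  if (length(trials) > 0L) {
    stopifnot(all(vapply(trials, inherits, logical(1), "semg_trial")))
    fs <- vapply(trials, function(t) t$fs, numeric(1))
    if (length(unique(fs)) != 1L) stop("fs must be constant within a trialset")
    nch <- vapply(trials, function(t) ncol(t$samples), integer(1))
    if (length(unique(nch)) != 1L) stop("channel count must be constant within a trialset")
    labs <- vapply(trials, function(t) t$label, integer(1))
    if (is.null(n_classes)) n_classes <- max(labs) + 1L
    if (any(labs < 0L | labs >= n_classes)) stop("labels must lie in [0, n_classes)")
    if (!is.null(channel_names) && length(channel_names) != nch[1L])
      stop("channel_names length mismatch")
  } else if (is.null(n_classes)) n_classes <- 0L
  structure(list(trials = trials, n_classes = as.integer(n_classes),
                 channel_names = channel_names),
            class = "semg_trialset")
}

#' @export
print.semg_trialset <- function(x, ...) {
  if (length(x$trials) == 0L) {
    cat("<semg_trialset> empty\n"); return(invisible(x))
  }
  t1 <- x$trials[[1L]]
  cat(sprintf("<semg_trialset> %d trials, %d classes, %d channels @ %g Hz\n",
              length(x$trials), x$n_classes, ncol(t1$samples), t1$fs))
  invisible(x)
}

#' @export
length.semg_trialset <- function(x) length(x$trials)

#' Labels of a trialset
#' @param ts A [trialset()].
#' @return Integer vector of 0-based labels.
#' @export
trial_labels <- function(ts) {
  vapply(ts$trials, function(t) t$label, integer(1))
}

#' Read a trialset from a manifest CSV
#'
#' The manifest has columns `trial_path,subject_id,label`; each `trial_path`
#' is a headerless numeric CSV (rows = samples, columns = channels), relative
#' to the manifest's directory unless absolute. Labels are mapped to a
#' contiguous 0-based index; the mapping is kept in the `label_map` attribute
#' (original label values in index order).
#'
#' @param manifest_path Path to the manifest CSV.
#' @param fs Sampling rate to stamp on the trials (the CSV dialect carries no
#'   rate). Default 4000 Hz.
#' @return A [trialset()] with attribute `label_map`.
#' @export
read_trialset <- function(manifest_path, fs = 4000) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("trial_path", "subject_id", "label")
  if (!all(need %in% names(man))) stop("manifest must have columns ", paste(need, collapse = ","))
  base <- dirname(manifest_path)
  lab_raw <- man$label
  label_map <- sort(unique(lab_raw))
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$trial_path[i]
    if (!file.path_is_absolute(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("trial file not found: ", p)
    m <- tryCatch(as.matrix(utils::read.csv(p, header = FALSE)),
                  warning = function(w) stop("malformed trial CSV: ", p))
    if (!is.numeric(m) || anyNA(m))
      stop("non-numeric or ragged trial CSV: ", p,
           " (first bad row ", which(apply(is.na(m), 1, any))[1], ")")
    trials[[i]] <- trial(m, fs = fs,
                         label = match(lab_raw[i], label_map) - 1L,
                         subject = man$subject_id[i])
  }
  if (length(trials) > 1L) {
    nch <- vapply(trials, function(t) ncol(t$samples), integer(1))
    if (length(unique(nch)) != 1L)
      stop("inconsistent channel count across trials: ", paste(unique(nch), collapse = ","))
  }
  ts <- trialset(trials, n_classes = max(length(label_map), 1L))
  attr(ts, "label_map") <- label_map
  ts
}

file.path_is_absolute <- function(p) grepl("^(/|[A-Za-z]:)", p)

#' Write a trialset as trial CSVs plus a manifest
#'
#' Inverse of [read_trialset()]: one headerless numeric CSV per trial and a
#' `manifest.csv` with columns `trial_path,subject_id,label`. Values are
#' written at full double precision so the round trip is lossless.
#'
#' @param ts A [trialset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_trialset <- function(ts, dir) {
  stopifnot(inherits(ts, "semg_trialset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  n <- length(ts$trials)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- sprintf("trial_%04d.csv", i)
    m <- ts$trials[[i]]$samples
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(dir, paths[i]), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  man <- data.frame(trial_path = paths,
                    subject_id = vapply(ts$trials, function(t) t$subject, character(1)),
                    label = vapply(ts$trials, function(t) t$label, integer(1)))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Plan sliding windows over a trial
#'
#' Windows are half-open sample ranges `[i*hop, i*hop + window_length)`,
#' 0-based, `i = 0..T-1`, with `T = floor((n_samples - window_length)/hop) + 1`.
#'
#' @param n_samples Trial length in samples.
#' @param window_length Window length in samples (>= 2).
#' @param hop Hop between window starts in samples (>= 1).
#' @return A `window_plan` with fields `window_length`, `hop`, `T`, `starts`
#'   (0-based window start samples).
#' @export
plan_windows <- function(n_samples, window_length, hop = window_length) {
  n_samples <- as.integer(n_samples); window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (window_length < 2L || hop < 1L) stop("window_length >= 2 and hop >= 1 required")
  if (window_length > n_samples) stop("window_length exceeds n_samples")
  T <- (n_samples - window_length) %/% hop + 1L
  structure(list(window_length = window_length, hop = hop, T = T,
                 starts = (seq_len(T) - 1L) * hop),
            class = "window_plan")
}

# Extract window t (1-based) of a sample matrix under a plan.
window_slice <- function(samples, plan, t) {
  s <- plan$starts[t]
  samples[(s + 1L):(s + plan$window_length), , drop = FALSE]
}

#' ICA artifact removal for a trialset
#'
#' Per trial: channels are centered and whitened, unmixed by a fixed-point
#' ICA with symmetric decorrelation (tanh contrast), and components whose
#' absolute excess kurtosis exceeds `kurtosis_threshold` are zeroed before
#' projecting back to channel space. Heavy-tailed spike-like artifacts have
#' large kurtosis and are removed; with `kurtosis_threshold = Inf` the
#' round trip is an identity (up to numerical precision).
#'
#' @param ts A [trialset()].
#' @param n_components `"all"` or an integer `<= n_channels`; fewer components
#'   restricts the whitening to the leading principal subspace.
#' @param kurtosis_threshold Zero components with `|excess kurtosis|` above
#'   this (default 8).
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the random orthogonal initialisation.
#' @return A trialset of the same shape with cleaned samples.
#' @export
ica_preprocess <- function(ts, n_components = "all", kurtosis_threshold = 8,
                           max_iter = 200L, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(ts, "semg_trialset"))
  out <- ts
  for (i in seq_along(ts$trials)) {
    tr <- ts$trials[[i]]
    out$trials[[i]]$samples <- ica_clean_matrix(
      tr$samples, n_components, kurtosis_threshold, max_iter, tol,
      seed = seed + i - 1L)
  }
  out
}

ica_clean_matrix <- function(X, n_components, kurtosis_threshold, max_iter, tol, seed) {
  n <- nrow(X); ch <- ncol(X)
  if (ch == 1L) {
    message("single-channel trial passed through ica_preprocess unchanged")
    return(X)
  }
  if (n <= ch) stop("ICA needs n_samples > n_channels")
  r <- if (identical(n_components, "all")) ch else as.integer(n_components)
  if (r > ch) stop("n_components exceeds n_channels")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (n - 1L)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[r] < 1e-12 * max(eg$values))
    stop("rank-deficient channel covariance; use fewer components")
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  lam <- eg$values[seq_len(r)]
  K <- E %*% diag(1 / sqrt(lam), r)        # whitening: Z = Xc K
  Z <- Xc %*% K
  W <- with_seed(seed, {
    M <- matrix(stats::rnorm(r * r), r, r)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                       # n x r component estimates
    G <- tanh(WX)
    gp <- colMeans(1 - G^2)
    W_new <- crossprod(G, Z) / n - diag(gp, r) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("ICA did not converge in ", max_iter, " iterations; using best iterate")
  S <- Z %*% t(W)                          # independent components
  kurt <- apply(S, 2L, excess_kurtosis)
  drop <- abs(kurt) > kurtosis_threshold
  if (any(drop)) S[, drop] <- 0
  # back-projection: Z_hat = S W; Xc_hat = Z_hat Lambda^(1/2) E^T
  Xhat <- S %*% W %*% diag(sqrt(lam), r) %*% t(E)
  sweep(Xhat, 2L, -mu)
}
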