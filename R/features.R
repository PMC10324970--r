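#' Feature matrix with aligned labels
#'
#' The interchange object between feature stages and classifiers: one row per
#' trial, one column per feature, plus a 0-based integer label per row.
#'
#' @param x Numeric matrix (trials x features).
#' @param labels Integer vector of 0-based labels, one per row.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("labels must align with feature rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(as.data.frame(x$x), label = x$labels)
}

#' Write / read a feature matrix as CSV
#'
#' Rows are trials, the header carries feature names, and the final column
#' `label` holds the 0-based class index.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- utils::read.csv(path)
  if (!"label" %in% names(d)) stop("feature CSV must have a 'label' column")
  feature_matrix(as.matrix(d[setdiff(names(d), "label")]), d$label)
}

#' Per-channel summary features of a trialset
#'
#' The default per-trial row vector for manifold reduction: RMS, variance,
#' waveform length (mean absolute first difference) and zero-crossing count
#' per channel, giving `4 * n_channels` dimensions.
#'
#' @param ts A [trialset()].
#' @return A [feature_matrix()].
#' @export
trial_features <- function(ts) {
  stopifnot(inherits(ts, "semg_trialset"))
  rows <- t(vapply(ts$trials, function(tr) {
    X <- tr$samples
    unlist(lapply(seq_len(ncol(X)), function(ch) {
      x <- X[, ch]
      c(rms = sqrt(mean(x^2)),
        var = stats::var(x),
        wl = mean(abs(diff(x))),
        zc = sum(diff(sign(x - mean(x))) != 0))
    }))
  }, numeric(4L * ncol(ts$trials[[1L]]$samples))))
  colnames(rows) <- paste0(rep(c("rms", "var", "wl", "zc"), ncol(ts$trials[[1L]]$samples)),
                           "_ch", rep(seq_len(ncol(ts$trials[[1L]]$samples)), each = 4L))
  feature_matrix(rows, trial_labels(ts))
}
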