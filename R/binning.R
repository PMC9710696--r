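# Agglomerative binning of per-sequence feature vectors.

#' Bin feature vectors by Ward agglomerative clustering
#'
#' Bottom-up agglomerative clustering on Euclidean distances with Ward
#' linkage (the standard Lance-Williams recurrence on squared distances, as
#' implemented by `hclust(method = "ward.D2")`), cut at `n_bins` clusters.
#' The true number of bins is an input; no automatic model selection or
#' outlier detection is attempted.
#'
#' @param features n x D numeric matrix, one row per sequence; row names are
#'   the sequence ids.
#' @param n_bins Target number of bins, 1 <= n_bins <= n.
#' @return Named integer vector of bin labels in 1..n_bins.
#' @export
agglomerative_bin <- function(features, n_bins) {
  stopifnot(is.matrix(features) || is.data.frame(features))
  features <- as.matrix(features)
  if (!all(is.finite(features))) {
    stop("feature matrix contains non-finite entries")
  }
  ids <- rownames(features)
  if (!is.null(ids) && anyDuplicated(ids)) {
    stop("duplicate sequence ids in feature matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- nrow(features)
  if (n_bins < 1L || n_bins > n) {
    stop("n_bins must be between 1 and the number of sequences (", n,
         "), got ", n_bins)
  }
  if (n_bins == n) {
    labels <- seq_len(n)
  } else if (n_bins == 1L) {
    labels <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::dist(features), method = "ward.D2")
    labels <- stats::cutree(hc, k = n_bins)
  }
  stats::setNames(as.integer(labels), ids)
}
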