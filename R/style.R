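# Genomic style: Gram matrices of CNN feature maps, averaged over a
# sequence's scanning windows, flattened row-by-row into the binning feature.

#' Gram (style) matrix of a feature-map matrix
#'
#' For an Nl x Ml matrix of feature maps, entry (i, j) is the inner product
#' of map i and map j over all positions. Unnormalized by default; set
#' `normalize = TRUE` to divide by Nl * Ml (off by default because all
#' windows of one layer share a single Ml, so averaging raw Grams is
#' well-defined).
#'
#' @param feature_maps Nl x Ml numeric matrix (one feature map per row).
#' @param normalize Divide by Nl * Ml.
#' @return Symmetric positive semi-definite Nl x Nl matrix.
#' @export
gram <- function(feature_maps, normalize = FALSE) {
  stopifnot(is.matrix(feature_maps), nrow(feature_maps) >= 1L,
            ncol(feature_maps) >= 1L)
  G <- tcrossprod(feature_maps)
  if (normalize) G <- G / (nrow(feature_maps) * ncol(feature_maps))
  G
}

# Row-major flattening: rows of the matrix listed in order.
flatten_rows <- function(M) as.vector(t(M))

# Shared batched engine for style and feature-map features. Sequences are
# windowed (1024/500 by default), windows are run through the network in
# chunks, and per-window features (Gram rows or flattened maps) are averaged
# per sequence.
sequence_features <- function(model, seqs, layer,
                              type = c("style", "feature_map"),
                              window_length = NULL, stride = 500L,
                              chunk_windows = 64L, normalize = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(model, "feature_cnn"), layer %in% 1:8,
            length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  }
  W <- if (is.null(window_length)) model$config$input_length else window_length
  stopifnot(W == model$config$input_length)
  Nl <- model$config$n_filters[layer]
  Ml <- model$config$map_sizes[layer]
  dim_out <- if (type == "style") Nl * Nl else Nl * Ml
  n <- length(seqs)
  acc <- matrix(0, n, dim_out)
  n_windows <- integer(n)
  # per-sequence window code matrices, processed in chunks of windows
  pending_codes <- vector("list", 0L)
  pending_owner <- integer(0)
  flush <- function(codes_list, owners) {
    codes <- do.call(cbind, codes_list)
    B <- ncol(codes)
    X <- codes_to_one_hot(codes)
    fwd <- cnn_forward(model, X, B, training = FALSE, record_layers = layer)
    maps <- fwd$maps[[as.character(layer)]]       # Nl x Ml x B
    for (w in seq_len(B)) {
      Fm <- matrix(maps[, , w], Nl, Ml)
      feat <- if (type == "style") flatten_rows(gram(Fm, normalize = normalize))
              else flatten_rows(Fm)
      acc[owners[w], ] <<- acc[owners[w], ] + feat
    }
  }
  buffered <- 0L
  for (i in seq_len(n)) {
    codes <- dna_codes(normalize_dna(seqs[[i]]))
    wm <- window_code_matrix(codes, W, stride)
    n_windows[i] <- ncol(wm)
    pending_codes[[length(pending_codes) + 1L]] <- wm
    pending_owner <- c(pending_owner, rep(i, ncol(wm)))
    buffered <- buffered + ncol(wm)
    if (buffered >= chunk_windows) {
      flush(pending_codes, pending_owner)
      pending_codes <- vector("list", 0L)
      pending_owner <- integer(0)
      buffered <- 0L
    }
  }
  if (buffered > 0L) flush(pending_codes, pending_owner)
  out <- acc / n_windows
  rownames(out) <- names(seqs)
  attr(out, "layer") <- as.integer(layer)
  attr(out, "n_windows") <- stats::setNames(n_windows, names(seqs))
  attr(out, "feature_type") <- type
  out
}

#' Style vectors for a set of sequences
#'
#' Each sequence is scanned with 1024 bp windows shifted by 500 bp, the Gram
#' matrix of the chosen layer's feature maps is computed per window, the
#' Grams are averaged elementwise, and the rows of the averaged matrix are
#' listed in order to form the feature vector.
#'
#' @param model A trained `feature_cnn`.
#' @param seqs Named character vector of sequences.
#' @param layer Layer index in 1..8 (style is usually taken from 1..6).
#' @param stride Window shift in bp (default 500).
#' @param normalize Normalize each Gram by Nl * Ml (default FALSE).
#' @return n x Nl^2 matrix, one row per sequence, with attributes `layer`
#'   and `n_windows`.
#' @export
style_features <- function(model, seqs, layer, stride = 500L,
                           normalize = FALSE) {
  sequence_features(model, seqs, layer, type = "style", stride = stride,
                    normalize = normalize)
}

#' Flattened feature-map vectors (baseline contrast to style)
#'
#' The row-listed post-ReLU feature maps themselves, without the Gram step.
#' Used to demonstrate that raw feature maps, unlike their correlations, are
#' poor binning features. By default (`windows = "first"`) the maps of the
#' sequence's first scanning window are used: the scan-and-average construct
#' belongs to the style matrix, and a window average of raw maps is no
#' longer "feature maps alone" but a first-order frequency summary of them
#' (see the vignette). `windows = "average"` gives that averaged variant.
#'
#' @inheritParams style_features
#' @param windows `"first"` (default) or `"average"` over scanning windows.
#' @return n x (Nl * Ml) matrix with attributes as in [style_features()].
#' @export
feature_map_features <- function(model, seqs, layer, stride = 500L,
                                 windows = c("first", "average")) {
  windows <- match.arg(windows)
  if (windows == "first") {
    W <- model$config$input_length
    seqs <- stats::setNames(substr(seqs, 1L, W), names(seqs))
  }
  sequence_features(model, seqs, layer, type = "feature_map", stride = stride)
}

#' Style vector of a single sequence
#'
#' @inheritParams style_features
#' @param seq A single residue string.
#' @param id Sequence id recorded on the result.
#' @return Numeric vector of length Nl^2 with attributes `layer`,
#'   `source_id` and `n_windows_averaged`.
#' @export
style_of_sequence <- function(model, seq, layer, id = "seq", stride = 500L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  m <- style_features(model, stats::setNames(seq, id), layer, stride = stride)
  structure(as.numeric(m[1L, ]), layer = as.integer(layer), source_id = id,
            n_windows_averaged = unname(attr(m, "n_windows")[1L]))
}

#' Coverage scale statistics for a dataset
#'
#' Calibrates the coverage dimension against the style features: records the
#' dataset mean and (population) standard deviation of coverage and the mean
#' per-dimension population standard deviation of the style vectors.
#'
#' @param features n x D style feature matrix for the dataset being binned.
#' @param coverages Nonnegative numeric vector of per-sequence coverages.
#' @return List with `mean_cov`, `sd_cov`, `style_sd_mean`.
#' @export
coverage_scale_stats <- function(features, coverages) {
  stopifnot(is.matrix(features), length(coverages) == nrow(features))
  if (any(coverages < 0)) stop("negative coverage value(s)")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(mean_cov = mean(coverages), sd_cov = pop_sd(coverages),
       style_sd_mean = mean(apply(features, 2L, pop_sd)))
}

#' Append a scaled coverage dimension to a style vector
#'
#' The appended entry is `((coverage - mean_cov) / sd_cov) * style_sd_mean`,
#' i.e. the dataset z-score of the coverage times the mean per-dimension
#' spread of the style vectors, which makes the extra dimension commensurate
#' with a typical style dimension. If the dataset coverage is constant
#' (`sd_cov = 0`) the appended entry is 0.
#'
#' @param vec Style vector (numeric).
#' @param coverage Nonnegative coverage value.
#' @param scale_stats Result of [coverage_scale_stats()] for the dataset.
#' @return Numeric vector of length `length(vec) + 1`.
#' @export
augment_with_coverage <- function(vec, coverage, scale_stats) {
  if (coverage < 0) stop("negative coverage value")
  z <- if (scale_stats$sd_cov == 0) 0
       else (coverage - scale_stats$mean_cov) / scale_stats$sd_cov
  c(as.numeric(vec), z * scale_stats$style_sd_mean)
}

#' Append the scaled coverage dimension to a whole feature table
#'
#' @param features n x D style feature matrix.
#' @param coverages Nonnegative coverage vector aligned with the rows.
#' @return n x (D + 1) matrix.
#' @export
augment_features <- function(features, coverages) {
  st <- coverage_scale_stats(features, coverages)
  z <- if (st$sd_cov == 0) rep(0, nrow(features))
       else (coverages - st$mean_cov) / st$sd_cov
  out <- cbind(features, coverage = z * st$style_sd_mean)
  rownames(out) <- rownames(features)
  out
}
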