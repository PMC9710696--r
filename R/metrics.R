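# Clustering evaluation: pair counting (Rand index, adjusted Rand index,
# pair F-measure) and entropy-based homogeneity / completeness.

#' Pairwise agreement counts between two labelings
#'
#' Counts unordered pairs of elements: TP = same true class and same
#' predicted cluster, TN = different class and different cluster, FP =
#' different class but same cluster, FN = same class but different cluster.
#' Computed exactly from the contingency table.
#'
#' @param true_labels,pred_labels Equal-length, nonempty label vectors.
#' @return List with integer-valued `TP`, `TN`, `FP`, `FN` summing to
#'   n(n-1)/2.
#' @export
pair_counts <- function(true_labels, pred_labels) {
  check_labels(true_labels, pred_labels)
  n <- length(true_labels)
  ct <- table(true_labels, pred_labels)
  tp <- sum(choose(ct, 2L))
  same_true <- sum(choose(rowSums(ct), 2L))
  same_pred <- sum(choose(colSums(ct), 2L))
  total <- choose(n, 2L)
  list(TP = tp, FN = same_true - tp, FP = same_pred - tp,
       TN = total - same_true - same_pred + tp)
}

check_labels <- function(true_labels, pred_labels) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors have different lengths (", length(true_labels),
         " vs ", length(pred_labels), ")")
  }
  invisible(NULL)
}

#' Rand index
#'
#' (TP + TN) / all pairs. Returns 1 for a single element (no pairs).
#'
#' @inheritParams pair_counts
#' @export
rand_index <- function(true_labels, pred_labels) {
  pc <- pair_counts(true_labels, pred_labels)
  total <- pc$TP + pc$TN + pc$FP + pc$FN
  if (total == 0) return(1)
  (pc$TP + pc$TN) / total
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' The Rand index corrected for chance agreement under the permutation
#' (hypergeometric) null, computed with the contingency-table closed form
#' ARI = (RI - E[RI]) / (max RI - E[RI]). Returns 1 in the degenerate cases
#' where both labelings are all-identical or both are all-singletons.
#'
#' @inheritParams pair_counts
#' @export
adjusted_rand_index <- function(true_labels, pred_labels) {
  pc <- pair_counts(true_labels, pred_labels)
  total <- pc$TP + pc$TN + pc$FP + pc$FN
  if (total == 0) return(1)
  sum_a <- pc$TP + pc$FN
  sum_b <- pc$TP + pc$FP
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (pc$TP - expected) / (max_index - expected)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Entropy-based homogeneity and completeness
#'
#' Homogeneity = 1 - H(true | predicted) / H(true): each predicted bin
#' contains members of a single true class. Completeness =
#' 1 - H(predicted | true) / H(predicted): members of one true class land in
#' a single bin. Entropies are natural-log (the ratios are base-invariant);
#' a score is 1 by convention when its unconditional entropy is 0.
#'
#' @inheritParams pair_counts
#' @return List with `homogeneity` and `completeness`, both in [0, 1].
#' @export
homogeneity_completeness <- function(true_labels, pred_labels) {
  check_labels(true_labels, pred_labels)
  ct <- unclass(table(true_labels, pred_labels))
  n <- sum(ct)
  h_true <- entropy_nat(rowSums(ct))
  h_pred <- entropy_nat(colSums(ct))
  # conditional entropies from the joint table
  cond <- function(margin_sums, by_col) {
    tot <- 0
    k <- if (by_col) ncol(ct) else nrow(ct)
    for (j in seq_len(k)) {
      slice <- if (by_col) ct[, j] else ct[j, ]
      m <- sum(slice)
      if (m > 0) tot <- tot + (m / n) * entropy_nat(slice)
    }
    tot
  }
  h_true_given_pred <- cond(NULL, by_col = TRUE)
  h_pred_given_true <- cond(NULL, by_col = FALSE)
  list(homogeneity = if (h_true == 0) 1 else 1 - h_true_given_pred / h_true,
       completeness = if (h_pred == 0) 1 else 1 - h_pred_given_true / h_pred)
}

#' Pairwise F-measure
#'
#' Harmonic mean of pairwise recall TP/(TP+FN) and precision TP/(TP+FP);
#' 0 by convention when TP = 0.
#'
#' @param counts Pair counts from [pair_counts()].
#' @export
pair_f_measure <- function(counts) {
  if (counts$TP == 0) return(0)
  rec <- counts$TP / (counts$TP + counts$FN)
  pre <- counts$TP / (counts$TP + counts$FP)
  2 * rec * pre / (rec + pre)
}

#' All clustering scores for a predicted vs. true labeling
#'
#' @inheritParams pair_counts
#' @return List with `rand_index`, `ari`, `homogeneity`, `completeness`,
#'   `f_measure`, plus `n`, `n_bins_true`, `n_bins_pred`.
#' @export
clustering_scores <- function(true_labels, pred_labels) {
  pc <- pair_counts(true_labels, pred_labels)
  hc <- homogeneity_completeness(true_labels, pred_labels)
  list(rand_index = rand_index(true_labels, pred_labels),
       ari = adjusted_rand_index(true_labels, pred_labels),
       homogeneity = hc$homogeneity,
       completeness = hc$completeness,
       f_measure = pair_f_measure(pc),
       n = length(true_labels),
       n_bins_true = length(unique(true_labels)),
       n_bins_pred = length(unique(pred_labels)))
}
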