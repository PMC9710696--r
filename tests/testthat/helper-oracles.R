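# Independent brute-force oracles, deliberately naive and separate from the
# package implementation paths they check.

# Gram matrix by explicit double loop.
oracle_gram <- function(F) {
  Nl <- nrow(F)
  G <- matrix(0, Nl, Nl)
  for (i in seq_len(Nl))
    for (j in seq_len(Nl))
      G[i, j] <- sum(F[i, ] * F[j, ])
  G
}

# Stride-1 "same" cross-correlation of a multi-channel filter bank with a
# multi-channel input, by triple loop; matches the convention of the
# network's first layer (left pad floor((d-1)/2), zero padding).
oracle_conv <- function(W, b, X) {
  dims <- dim(W)
  Fl <- dims[1]; C <- dims[2]; d <- dims[3]
  P <- ncol(X)
  pad_l <- (d - 1) %/% 2
  out <- matrix(0, Fl, P)
  for (f in seq_len(Fl)) {
    for (p in seq_len(P)) {
      acc <- b[f]
      for (t in seq_len(d)) {
        src <- p + t - 1 - pad_l
        if (src >= 1 && src <= P) {
          acc <- acc + sum(W[f, , t] * X[, src])
        }
      }
      out[f, p] <- acc
    }
  }
  out
}

# Pair counts by explicit O(n^2) loop over all unordered pairs.
oracle_pair_counts <- function(truth, pred) {
  n <- length(truth)
  tp <- tn <- fp <- fn <- 0L
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        st <- truth[i] == truth[j]
        sp <- pred[i] == pred[j]
        if (st && sp) tp <- tp + 1L
        else if (!st && !sp) tn <- tn + 1L
        else if (!st && sp) fp <- fp + 1L
        else fn <- fn + 1L
      }
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Ward agglomerative clustering by the explicit Lance-Williams recurrence on
# squared Euclidean distances; returns the membership partition at k
# clusters. Ties are broken by the smallest (i, j) pair, which coincides
# with hclust for distinct merge costs.
oracle_ward <- function(X, k) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  while (length(active) > k) {
    best <- c(NA, NA)
    best_cost <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          i <- active[a]; j <- active[b]
          # the Lance-Williams recursion below keeps D2 equal to the Ward
          # merge criterion (twice the within-cluster variance increase)
          cost <- D2[i, j]
          if (cost < best_cost - 1e-12) {
            best_cost <- cost
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    # Lance-Williams update of squared distances to the merged cluster
    for (m in active) {
      if (m != i && m != j) {
        ni <- sizes[i]; nj <- sizes[j]; nm <- sizes[m]
        D2[i, m] <- D2[m, i] <-
          ((ni + nm) * D2[i, m] + (nj + nm) * D2[j, m] - nm * D2[i, j]) /
          (ni + nj + nm)
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  labels <- integer(n)
  for (a in seq_along(active)) labels[members[[active[a]]]] <- a
  labels
}

# k-mer counting with a plain dictionary, skipping windows containing N.
oracle_kmer <- function(seq, k) {
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  counts <- setNames(numeric(length(words)), sort(words))
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (s in seq_len(length(chars) - k + 1)) {
    w <- paste(chars[s:(s + k - 1)], collapse = "")
    if (!grepl("N", w, fixed = TRUE)) {
      counts[w] <- counts[w] + 1
      total <- total + 1
    }
  }
  if (total > 0) counts <- counts / total
  counts
}

# Sequence with prescribed GC fraction signal, for quick fixtures.
random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

gc_fraction <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  mean(chars %in% c("G", "C"))
}
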