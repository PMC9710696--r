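# k-mer frequency baseline: the conventional composition feature the style
# vectors are compared against.

#' k-mer frequency profile of a sequence
#'
#' Counts every length-k window at offsets 0..L-k (shift-by-one scanning) on
#' the given strand only (no reverse-complement canonicalization) and
#' normalizes by the total number of counted windows. Windows containing `N`
#' are skipped. If every window contains an `N`, a zero profile is returned
#' with attribute `all_invalid = TRUE`.
#'
#' @param seq A residue string of length >= k.
#' @param k Word length (>= 1).
#' @return Named numeric vector of length 4^k in lexicographic A/C/G/T
#'   order, summing to 1 (unless all windows are invalid).
#' @export
kmer_profile <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  seq <- normalize_dna(seq)
  if (nchar(seq) < k) {
    stop("sequence length (", nchar(seq), ") is shorter than k (", k, ")")
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  total <- sum(counts)
  if (total == 0L) {
    out <- counts * 0
    attr(out, "all_invalid") <- TRUE
    return(out)
  }
  counts / total
}

#' k-mer frequency profiles for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param k Word length.
#' @return n x 4^k matrix of frequencies, rows named by sequence id.
#' @export
kmer_features <- function(seqs, k) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  short <- nchar(seqs) < k
  if (any(short)) {
    stop("sequence(s) shorter than k: ",
         paste(names(seqs)[short], collapse = ", "))
  }
  set <- Biostrings::DNAStringSet(normalize_dna(seqs))
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  totals <- rowSums(counts)
  freqs <- counts / pmax(totals, 1L)
  rownames(freqs) <- names(seqs)
  attr(freqs, "all_invalid") <- stats::setNames(totals == 0L, names(seqs))
  freqs
}
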