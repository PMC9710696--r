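#' @importFrom stats rnorm runif rgamma sd setNames dist hclust cutree
#' @importFrom Rcpp evalCpp
#' @importFrom data.table fread fwrite data.table
#' @useDynLib stylebin, .registration = TRUE
NULL

# Canonical nucleotide row order used everywhere in the package.
DNA_ROWS <- c("A", "C", "G", "T")

#' Normalize a DNA residue string
#'
#' Uppercases and maps every character outside {A, C, G, T} (i.e. all IUPAC
#' ambiguity codes and anything else) to `N`.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of the same length, over the alphabet A/C/G/T/N.
#' @export
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# Integer codes A=1, C=2, G=3, T=4, N/other=0 for one sequence string.
dna_codes <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(v, DNA_ROWS)
  code[is.na(code)] <- 0L
  as.integer(code)
}

codes_to_string <- function(codes) {
  chars <- c("N", DNA_ROWS)[codes + 1L]
  paste(chars, collapse = "")
}

#' Read a FASTA file of DNA sequences
#'
#' Residues are normalized (uppercase; non-ACGT characters become `N`).
#' Sequence ids are the FASTA header up to the first whitespace. Gzip
#' compressed files are handled transparently.
#'
#' @param path Path to a FASTA (or FASTA.gz) file.
#' @return Named character vector of normalized residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_dna(as.character(set))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[empty], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' One-hot encode a DNA sequence
#'
#' Encodes a residue string as a 4 x L binary matrix with rows in the fixed
#' order (A, C, G, T). `N` (and anything normalized to it) becomes an
#' all-zero column, so ambiguous bases contribute nothing to convolutions.
#'
#' @param seq A single residue string.
#' @return 4 x L numeric matrix with rownames A/C/G/T.
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  codes <- dna_codes(normalize_dna(seq))
  codes_to_one_hot(matrix(codes, ncol = 1L))[, , drop = FALSE]
}

# Batched one-hot: codes is an L x B integer matrix (0 = N); returns a
# 4 x (L*B) matrix, block-major (columns of window b occupy (b-1)*L + 1..L).
codes_to_one_hot <- function(codes) {
  L <- nrow(codes)
  B <- ncol(codes)
  X <- matrix(0, 4L, L * B)
  nz <- which(codes > 0L)
  if (length(nz)) {
    X[(nz - 1L) * 4L + codes[nz]] <- 1
  }
  rownames(X) <- DNA_ROWS
  X
}

#' Decode a one-hot matrix back to residues
#'
#' Columns with no nonzero entry decode to `N`.
#'
#' @param mat 4 x L one-hot matrix (row order A, C, G, T).
#' @return Residue string.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  codes <- apply(mat, 2L, function(col) {
    if (all(col == 0)) 0L else which.max(col)
  })
  codes_to_string(as.integer(codes))
}

# 0-based start offsets of scanning windows; single start 0 for short input.
window_starts <- function(len, window_length, stride) {
  if (len < window_length) return(0L)
  as.integer(seq.int(0L, len - window_length, by = stride))
}

#' Cut a sequence into fixed-length scanning windows
#'
#' Scans with windows of `window_length` bp shifted by `stride` bp. A trailing
#' remainder shorter than `window_length` is discarded; a sequence shorter
#' than `window_length` yields exactly one window right-padded with all-zero
#' columns.
#'
#' @param seq A residue string.
#' @param window_length Window size in bp (default 1024).
#' @param stride Shift between window starts in bp (default 500).
#' @return An object of class `window_set`: list with `windows` (list of
#'   4 x window_length one-hot matrices), `starts` (0-based offsets),
#'   `window_length` and `stride`.
#' @export
make_windows <- function(seq, window_length = 1024L, stride = 500L) {
  stopifnot(window_length >= 1L, stride >= 1L, nchar(seq) >= 1L)
  seq <- normalize_dna(seq)
  codes <- dna_codes(seq)
  starts <- window_starts(length(codes), window_length, stride)
  mats <- lapply(starts, function(s) {
    idx <- (s + 1L):min(s + window_length, length(codes))
    w <- codes[idx]
    if (length(w) < window_length) w <- c(w, rep(0L, window_length - length(w)))
    codes_to_one_hot(matrix(w, ncol = 1L))
  })
  structure(list(windows = mats, starts = starts,
                 window_length = as.integer(window_length),
                 stride = as.integer(stride)),
            class = "window_set")
}

# Window code matrix for one sequence: window_length x n_windows integer
# matrix (0-padded), used by the batched feature extractors.
window_code_matrix <- function(codes, window_length = 1024L, stride = 500L) {
  starts <- window_starts(length(codes), window_length, stride)
  out <- matrix(0L, window_length, length(starts))
  for (j in seq_along(starts)) {
    idx <- (starts[j] + 1L):min(starts[j] + window_length, length(codes))
    out[seq_along(idx), j] <- codes[idx]
  }
  out
}
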