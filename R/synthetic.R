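# Synthetic data generators: Markov "species" genomes with controlled GC and
# compositional texture, i.i.d. GC-content groups, and per-contig coverage.
# They provide labeled data with the statistical structure the binning method
# assumes, without any external downloads.

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not perturb user RNG.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

all_contexts <- function(order) {
  if (order == 0L) return("")
  grids <- rep(list(DNA_ROWS), order)
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Sample a synthetic species model
#'
#' Draws a Markov chain over A/C/G/T whose conditional next-base
#' distributions are Dirichlet perturbations of the GC-balanced base
#' distribution. Each row is rescaled so its G+C mass equals `gc_target`
#' exactly; the stationary GC fraction therefore equals the target by
#' construction. Larger `divergence` gives more species-specific texture
#' (codon-scale word preferences); as `divergence -> 0` the rows approach the
#' unperturbed base distribution.
#'
#' @param seed Integer seed; distinct seeds give distinct transition tables.
#' @param gc_target Stationary GC fraction, in (0, 1).
#' @param divergence Dispersion parameter (> 0) of the Dirichlet perturbation.
#' @param order Markov order (default 2).
#' @param species_id Optional id; defaults to `"species<seed>"`.
#' @return An object of class `species_model`: list with `species_id`,
#'   `order`, `gc_target` and `transitions` (4^order x 4 row-stochastic
#'   matrix, rows named by context, columns A/C/G/T).
#' @export
sample_species_model <- function(seed, gc_target, divergence = 0.1,
                                 order = 2L, species_id = NULL) {
  stopifnot(gc_target > 0, gc_target < 1, divergence > 0, order >= 0L)
  base <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  ctx <- all_contexts(order)
  trans <- with_seed(seed, function() {
    t(vapply(seq_along(ctx), function(i) {
      alpha <- base / divergence
      row <- rgamma(4L, shape = alpha, rate = 1)
      row <- row / sum(row)
      # pin the GC mass of every conditional to gc_target
      g <- row[2L] + row[3L]
      if (g <= 0 || g >= 1) row <- base
      else {
        row[c(2L, 3L)] <- row[c(2L, 3L)] * gc_target / g
        row[c(1L, 4L)] <- row[c(1L, 4L)] * (1 - gc_target) / (1 - g)
      }
      row
    }, numeric(4L)))
  })
  dimnames(trans) <- list(ctx, DNA_ROWS)
  structure(list(species_id = if (is.null(species_id))
                   paste0("species", seed) else species_id,
                 order = as.integer(order), gc_target = gc_target,
                 transitions = trans),
            class = "species_model")
}

#' Simulate a genome from a species model
#'
#' Draws `length` bases from the model's Markov chain. The first `order`
#' bases are drawn i.i.d. from the GC-balanced base distribution.
#'
#' @param model A `species_model`.
#' @param length Genome length in bp (>= order + 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Residue string of the requested length.
#' @export
simulate_genome <- function(model, length, seed) {
  stopifnot(inherits(model, "species_model"), length >= model$order + 1L)
  order <- model$order
  cum <- t(apply(model$transitions, 1L, cumsum))
  base <- c((1 - model$gc_target) / 2, model$gc_target / 2,
            model$gc_target / 2, (1 - model$gc_target) / 2)
  with_seed(seed, function() {
    codes <- integer(length)
    u <- runif(length)
    for (i in seq_len(min(order, length))) {
      codes[i] <- findInterval(u[i], cumsum(base)) + 1L
    }
    if (length > order) {
      if (order == 0L) {
        row <- cum[1L, ]
        codes[] <- findInterval(u, row) + 1L
      } else {
        pow <- 4L^((order - 1L):0L)
        for (i in (order + 1L):length) {
          ctx_idx <- sum((codes[(i - order):(i - 1L)] - 1L) * pow) + 1L
          codes[i] <- findInterval(u[i], cum[ctx_idx, ]) + 1L
        }
      }
    }
    codes[codes > 4L] <- 4L
    codes_to_string(codes)
  })
}

# Shared engine: simulate one genome per model and cut random fixed-length
# fragments with uniform random starts (with replacement).
sample_fragments <- function(models, n_per_species, fragment_length,
                             genome_length, seed) {
  stopifnot(length(models) >= 2L, n_per_species >= 1L)
  if (genome_length < fragment_length) {
    stop("genome length (", genome_length, ") is shorter than the fragment ",
         "length (", fragment_length, ")")
  }
  seqs <- character(0)
  labels <- character(0)
  for (m in seq_along(models)) {
    model <- models[[m]]
    genome <- simulate_genome(model, genome_length, seed + 7919L * m)
    starts <- with_seed(seed + 104729L * m, function() {
      sample.int(genome_length - fragment_length + 1L, n_per_species,
                 replace = TRUE)
    })
    frags <- substring(genome, starts, starts + fragment_length - 1L)
    names(frags) <- sprintf("%s_frag%04d", model$species_id,
                            seq_len(n_per_species))
    seqs <- c(seqs, frags)
    labels <- c(labels, rep(model$species_id, n_per_species))
  }
  labeled_dataset(seqs, labels)
}

labeled_dataset <- function(sequences, labels) {
  stopifnot(length(sequences) == length(labels), all(nzchar(labels)))
  structure(list(sequences = sequences, labels = as.character(labels)),
            class = "labeled_dataset")
}

#' Build a labeled pre-training set of 1024 bp windows
#'
#' Simulates one genome per species model and extracts `windows_per_species`
#' random 1024 bp substrings (uniform starts, with replacement), labeled by
#' species id.
#'
#' @param models List of `species_model` objects (>= 2).
#' @param windows_per_species Number of windows per species.
#' @param seed Integer seed.
#' @param window_length Window length in bp (default 1024).
#' @param genome_length Length of each simulated genome (default 102400).
#' @return A `labeled_dataset`: list with `sequences` (named character) and
#'   `labels`.
#' @export
make_pretraining_set <- function(models, windows_per_species, seed,
                                 window_length = 1024L,
                                 genome_length = 102400L) {
  sample_fragments(models, windows_per_species, window_length,
                   genome_length, seed)
}

#' Build a labeled benchmark set of contig-length fragments
#'
#' Like [make_pretraining_set()] but cuts longer, contig-like fragments
#' (default 5120 bp, i.e. several scanning windows each) for held-out
#' binning benchmarks.
#'
#' @inheritParams make_pretraining_set
#' @param n_per_species Number of contigs per species.
#' @param contig_length Contig length in bp (default 5120).
#' @export
make_contig_set <- function(models, n_per_species, seed,
                            contig_length = 5120L,
                            genome_length = 102400L) {
  sample_fragments(models, n_per_species, contig_length, genome_length, seed)
}

#' Generate the two random GC-content groups
#'
#' Group 1 sequences are i.i.d. bases with P(G) = P(C) = x/200 and
#' P(A) = P(T) = (100 - x)/200; group 2 uses 100 - x. Labels are
#' `"group1"` / `"group2"`.
#'
#' @param x GC percent of group 1 (0 < x < 100); group 2 gets 100 - x.
#' @param n_per_group Sequences per group (default 500).
#' @param seq_length Sequence length in bp (default 5120).
#' @param seed Integer seed.
#' @return A `labeled_dataset`.
#' @export
make_gc_groups <- function(x, n_per_group = 500L, seq_length = 5120L, seed = 1L) {
  stopifnot(x > 0, x < 100, n_per_group >= 1L, seq_length >= 1L)
  probs1 <- c((100 - x) / 200, x / 200, x / 200, (100 - x) / 200)
  probs2 <- probs1[c(2L, 1L, 1L, 2L)]
  with_seed(seed, function() {
    draw <- function(probs, tag) {
      codes <- sample.int(4L, n_per_group * seq_length, replace = TRUE,
                          prob = probs)
      mat <- matrix(codes, nrow = seq_length)
      seqs <- apply(mat, 2L, codes_to_string)
      names(seqs) <- sprintf("%s_seq%04d", tag, seq_len(n_per_group))
      seqs
    }
    g1 <- draw(probs1, "group1")
    g2 <- draw(probs2, "group2")
    labeled_dataset(c(g1, g2),
                    rep(c("group1", "group2"), each = n_per_group))
  })
}

#' Simulate per-sequence coverage values
#'
#' Coverage is the class abundance plus Gaussian noise, clipped at zero.
#'
#' @param labels Character vector of class labels.
#' @param abundance Named numeric vector of per-class mean coverages; every
#'   label must be present.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of nonnegative coverages, aligned with `labels`.
#' @export
simulate_coverage <- function(labels, abundance, noise_sd, seed = 1L) {
  stopifnot(noise_sd >= 0)
  missing <- setdiff(unique(labels), names(abundance))
  if (length(missing)) {
    stop("no abundance given for label(s): ", paste(missing, collapse = ", "))
  }
  with_seed(seed, function() {
    pmax(0, abundance[labels] + rnorm(length(labels), sd = noise_sd))
  })
}

#' Write a labeled dataset to FASTA plus truth (and optional coverage) tables
#'
#' @param dataset A `labeled_dataset`.
#' @param fasta Output FASTA path.
#' @param truth Output path for the tab-separated (sequence_id, label) table.
#' @param coverage Optional numeric coverage vector aligned with the dataset.
#' @param coverage_path Output path for the (sequence_id, coverage) table.
#' @export
write_labeled_dataset <- function(dataset, fasta, truth,
                                  coverage = NULL, coverage_path = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  write_fasta(dataset$sequences, fasta)
  data.table::fwrite(
    data.table::data.table(sequence_id = names(dataset$sequences),
                           label = dataset$labels),
    truth, sep = "\t")
  if (!is.null(coverage)) {
    stopifnot(!is.null(coverage_path),
              length(coverage) == length(dataset$sequences))
    data.table::fwrite(
      data.table::data.table(sequence_id = names(dataset$sequences),
                             coverage = as.numeric(coverage)),
      coverage_path, sep = "\t")
  }
  invisible(fasta)
}
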