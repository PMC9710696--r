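# stylebin

Unsupervised metagenome binning with **genomic style** features: Gram
matrices of convolutional feature maps, used in place of the k-mer frequency
profiles that conventional binners cluster.

## The problem and the idea

Binning groups assembled metagenomic contigs into bins intended to
correspond to single species. Alignment-free binners describe each contig by
a composition vector — classically the tetranucleotide frequency — and
cluster those vectors. `stylebin` implements an alternative feature borrowed
from neural style transfer. A small 1-D CNN (eight modules of convolution,
batch normalization, ReLU and max pooling, with a global-average-pooling +
softmax head) is pre-trained to classify bacterial species from one-hot
encoded 1024 bp DNA windows; its filters behave as position-weight-matrix
motif detectors. For a chosen layer *l* with feature maps
F<sup>(l)</sup> ∈ ℝ<sup>N<sub>l</sub>×M<sub>l</sub></sup>, the **style
matrix** is the Gram matrix

&nbsp;&nbsp;&nbsp;&nbsp;G<sub>ij</sub><sup>(l)</sup> = Σ<sub>k</sub>
F<sub>ik</sub><sup>(l)</sup> · F<sub>jk</sub><sup>(l)</sup>,

the inner products of all pairs of maps. It records which motif detectors
co-activate while discarding where they fire — a species-specific
"preference distribution over motifs" that generalizes k-mer frequencies.
Long contigs are scanned with 1024 bp windows shifted by 500 bp; per-window
style matrices are averaged, the rows of the average are listed in order,
and the resulting N<sub>l</sub>² vectors (optionally with one scaled
coverage dimension) are clustered by Ward agglomerative clustering into a
given number of bins. Predictions are scored with the Rand index, adjusted
Rand index, entropy-based homogeneity/completeness and the pair F-measure.

Everything runs offline: the package ships generators for synthetic species
genomes (order-2 Markov chains with controlled GC and word texture) and for
the two random GC-content groups used to probe what the style captures.
The CNN, including backpropagation, is implemented natively on BLAS matrix
products with RcppArmadillo kernels — no deep-learning framework required.

## Worked example

Two synthetic species, a small pre-training run, then style binning of
held-out contigs:

```r
library(stylebin)

models <- list(sample_species_model(1, gc_target = 0.45, species_id = "sp_low"),
               sample_species_model(2, gc_target = 0.60, species_id = "sp_high"))
train  <- make_pretraining_set(models, windows_per_species = 250, seed = 11)
cnn    <- build_model(feature_cnn_config(n_classes = 2, seed = 1))
cnn    <- train_cnn(cnn, train, epochs = 3, seed = 5)
tail(cnn$training_log, 1)
#>   epoch  train_loss holdout_accuracy
#> 3     3 0.005721486                1

contigs <- make_contig_set(models, n_per_species = 30, seed = 42)  # 5120 bp
feats   <- style_features(cnn, contigs$sequences, layer = 2)       # 60 x 4096
bins    <- agglomerative_bin(feats, n_bins = 2)
clustering_scores(contigs$labels, bins)[c("ari", "homogeneity",
                                          "completeness", "f_measure")]
#> $ari: 1   $homogeneity: 1   $completeness: 1   $f_measure: 1
```

The classifier reaches perfect holdout accuracy on the two-species task and
the layer-2 style vectors recover the two species exactly (all four scores
1.0; the 4-mer baseline `kmer_features(contigs$sequences, 4)` also scores
ARI 1.0 on this easy two-species toy). The same pipeline is available from
the shell via `inst/cli/stylebin.R` with subcommands
`simulate | pretrain | extract | bin | eval`, each writing tab-separated
files plus a resolved-config YAML for bit-identical re-runs.

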