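# Shared scaled-down study setup: a synthetic community of 8 Markov species
# spanning GC 0.35-0.65, and a feature-extraction CNN pre-trained on 500
# windows per species for 6 epochs. Training takes a few minutes, so the
# model and the GC-group experiment results are computed once per test run
# and cached.

.stylebin_test_cache <- new.env(parent = emptyenv())

community_species_models <- function() {
  gcs <- seq(0.35, 0.65, length.out = 8)
  lapply(1:8, function(i) {
    sample_species_model(100 + i, gcs[i], divergence = 0.1,
                         species_id = sprintf("sp%02d", i))
  })
}

pretrained_community_model <- function() {
  if (is.null(.stylebin_test_cache$model)) {
    models <- community_species_models()
    ds <- make_pretraining_set(models, 500, seed = 11)
    m <- build_model(feature_cnn_config(n_classes = 8, seed = 1))
    .stylebin_test_cache$model <- train_cnn(m, ds, epochs = 6, seed = 5)
  }
  .stylebin_test_cache$model
}

# Layer-2 style clustering of the two GC groups at x percent; memoized.
gc_group_scores <- function(x) {
  key <- paste0("gc", x)
  if (is.null(.stylebin_test_cache[[key]])) {
    model <- pretrained_community_model()
    ds <- make_gc_groups(x, n_per_group = 500, seq_length = 5120,
                         seed = 20 + x)
    feats <- style_features(model, ds$sequences, layer = 2)
    bins <- agglomerative_bin(feats, 2)
    .stylebin_test_cache[[key]] <- clustering_scores(ds$labels, bins)
  }
  .stylebin_test_cache[[key]]
}
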