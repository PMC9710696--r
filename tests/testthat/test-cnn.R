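# A tiny 8-module configuration that keeps gradient checks and oracle
# comparisons fast. Pooling only in the first modules so short inputs survive
# all eight stages.
tiny_config <- function(input_length = 8L, n_classes = 3L, n_filters = 3L,
                        seed = 42L) {
  feature_cnn_config(n_classes = n_classes, n_filters = n_filters,
                     filter_sizes = rep(3L, 8L),
                     pool_sizes = c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),
                     input_length = input_length, seed = seed)
}

ns <- asNamespace("stylebin")

test_that("model building is deterministic and shape-consistent", {
  cfg <- feature_cnn_config(n_classes = 5, seed = 7)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1, m2)
  expect_equal(dim(m1$layers[[1]]$W), c(64, 4, 8))
  expect_equal(dim(m1$layers[[2]]$W), c(64, 64, 4))
  expect_equal(dim(m1$fc$W), c(5, 64))
  expect_error(feature_cnn_config(n_classes = 2, input_length = 64),
               "configuration error")
})

test_that("feature maps have the configured shapes and are nonnegative", {
  m <- build_model(tiny_config())
  w <- one_hot_encode("ACGTACGT")
  maps <- extract_feature_maps(m, w)
  expect_named(maps, as.character(1:8))
  expect_equal(dim(maps[["1"]]), c(3, 8))
  expect_equal(dim(maps[["4"]]), c(3, 1))
  expect_true(all(vapply(maps, function(f) all(f >= 0), logical(1))))
  expect_identical(maps, extract_feature_maps(m, w))
  expect_error(extract_feature_maps(m, w[, 1:4]), "4 x 8")
})

test_that("an all-zero window yields ReLU(bias) maps at layer 1", {
  m <- build_model(tiny_config())
  m$layers[[1]]$b <- c(-1, 0.5, 2)
  zero <- matrix(0, 4, 8)
  maps <- extract_feature_maps(m, zero)
  # fresh batch-norm running stats are identity, so layer 1 = relu(b)
  expect_equal(maps[["1"]],
               matrix(pmax(0, c(-1, 0.5, 2) / sqrt(1 + 1e-5)), 3, 8))
})

test_that("layer-1 convolution matches the triple-loop oracle", {
  set.seed(31)
  for (rep in 1:5) {
    L <- 4L * sample(3:8, 1)     # divisible by the two pooling stages
    cfg <- feature_cnn_config(n_classes = 2, n_filters = 4,
                              filter_sizes = c(sample(c(3L, 5L, 8L), 1),
                                               rep(3L, 7)),
                              pool_sizes = c(2L, 2L, rep(1L, 6)),
                              input_length = L, seed = rep)
    m <- build_model(cfg)
    s <- random_dna(L)
    X <- one_hot_encode(s)
    got <- ns$conv_fwd_cpp(m$layers[[1]]$W, m$layers[[1]]$b, X, L, 1L)
    want <- oracle_conv(m$layers[[1]]$W, m$layers[[1]]$b, X)
    expect_equal(got, want, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  set.seed(7)
  B <- 5L
  codes <- matrix(sample(0:4, 8 * B, replace = TRUE), 8, B)
  X <- ns$codes_to_one_hot(codes)
  y <- sample(1:3, B, replace = TRUE)
  Y <- matrix(0, 3, B); Y[cbind(y, seq_len(B))] <- 1
  loss_of <- function(m) {
    fwd <- ns$cnn_forward(m, X, B, training = TRUE)
    probs <- ns$softmax_cols(fwd$logits)
    -sum(Y * log(pmax(probs, 1e-12))) / B
  }
  fwd <- ns$cnn_forward(m, X, B, training = TRUE)
  bwd <- ns$cnn_backward(m, fwd, Y, B)
  base <- loss_of(m)
  eps <- 1e-6
  check <- function(get, set, g) {
    p <- get(m)
    for (i in sample(length(p), min(6, length(p)))) {
      m2 <- m
      p2 <- p
      p2[i] <- p2[i] + eps
      m2 <- set(m2, p2)
      num <- (loss_of(m2) - base) / eps
      expect_lt(abs(num - g[i]) / max(1e-4, abs(g[i])), 2e-2)
    }
  }
  for (l in c(1L, 3L, 6L, 8L)) {
    check(function(m) m$layers[[l]]$W,
          function(m, p) { m$layers[[l]]$W[] <- p; m }, bwd$grads[[l]]$dW)
    check(function(m) m$layers[[l]]$gamma,
          function(m, p) { m$layers[[l]]$gamma <- p; m },
          bwd$grads[[l]]$dgamma)
    check(function(m) m$layers[[l]]$beta,
          function(m, p) { m$layers[[l]]$beta <- p; m }, bwd$grads[[l]]$dbeta)
    check(function(m) m$layers[[l]]$b,
          function(m, p) { m$layers[[l]]$b <- p; m }, bwd$grads[[l]]$db)
  }
  check(function(m) m$fc$W, function(m, p) { m$fc$W[] <- p; m }, bwd$fc$dW)
  check(function(m) m$fc$b, function(m, p) { m$fc$b <- p; m }, bwd$fc$db)
})

labeled_dataset_for_test <- function(seqs, labels) {
  structure(list(sequences = seqs, labels = labels),
            class = "labeled_dataset")
}

test_that("training separates two species with a strong GC gap", {
  models <- list(sample_species_model(1, 0.3, species_id = "low_gc"),
                 sample_species_model(2, 0.7, species_id = "high_gc"))
  ds <- make_pretraining_set(models, 250, seed = 5, genome_length = 51200L)
  m <- build_model(feature_cnn_config(n_classes = 2, seed = 1))

  expect_identical(train_cnn(m, ds, epochs = 0), m)   # no-op contract

  trained <- train_cnn(m, ds, epochs = 3, seed = 9)
  log <- trained$training_log
  expect_equal(nrow(log), 3)
  expect_gt(log$holdout_accuracy[3], 0.95)
  expect_lt(log$train_loss[3], log$train_loss[1])

  # shuffle stability: same init, different batch order
  trained2 <- train_cnn(m, ds, epochs = 3, seed = 10)
  expect_lt(abs(trained2$training_log$holdout_accuracy[3] -
                log$holdout_accuracy[3]), 0.05)

  expect_error(train_cnn(m, labeled_dataset_for_test(ds$sequences[1:10],
                                                     rep("one", 10))),
               "at least 2 classes")
})

test_that("checkpoints round trip bit-identically and validate on load", {
  m <- build_model(tiny_config())
  w <- one_hot_encode("ACGTACGT")
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(predict_logits(m, w), predict_logits(m2, w))
  expect_identical(m2$config$n_filters, m$config$n_filters)

  expect_error(load_checkpoint(f, n_classes = 7), "n_classes mismatch")
  bad <- withr::local_tempfile()
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), "checkpoint")
  other <- withr::local_tempfile()
  saveRDS(list(something = 1), other)
  expect_error(load_checkpoint(other), "not a stylebin checkpoint")
})
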