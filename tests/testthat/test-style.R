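small_model <- function(seed = 3L) {
  # 8-module net on 64 bp inputs: fast enough for per-test extraction
  build_model(feature_cnn_config(n_classes = 2, n_filters = 4,
                                 filter_sizes = c(5L, rep(3L, 7)),
                                 pool_sizes = c(2L, 2L, 2L, rep(1L, 5)),
                                 input_length = 64L, seed = seed))
}

test_that("gram matches direct summation on the worked example", {
  F <- rbind(c(1, 0, 2), c(0, 1, 1))
  expect_equal(gram(F), rbind(c(5, 2), c(2, 2)))
  expect_equal(gram(matrix(0, 2, 3)), matrix(0, 2, 2))
  expect_equal(gram(matrix(1, 1, 7)), matrix(7, 1, 1))
})

test_that("gram equals the brute-force double loop on random maps", {
  set.seed(12)
  for (rep in 1:8) {
    Nl <- sample(1:16, 1)
    Ml <- sample(1:64, 1)
    F <- matrix(rnorm(Nl * Ml), Nl, Ml)
    G <- gram(F)
    expect_equal(G, oracle_gram(F), tolerance = 1e-5)
    # symmetry and positive semi-definiteness
    expect_equal(G, t(G), tolerance = 1e-6)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-6 * max(abs(ev))))
    expect_true(all(diag(G) >= 0))
  }
})

test_that("gram is degree-2 homogeneous and position-permutation invariant", {
  set.seed(13)
  F <- matrix(rnorm(6 * 20), 6, 20)
  expect_equal(gram(3 * F), 9 * gram(F), tolerance = 1e-9)
  perm <- sample(20)
  expect_equal(gram(F[, perm]), gram(F), tolerance = 1e-9)
  expect_equal(gram(F, normalize = TRUE), gram(F) / (6 * 20))
})

test_that("style of a single-window sequence is that window's gram rows", {
  m <- small_model()
  s <- random_dna(64, seed = 21)
  v <- style_of_sequence(m, s, layer = 2)
  expect_equal(attr(v, "n_windows_averaged"), 1L)
  maps <- extract_feature_maps(m, one_hot_encode(s))
  G <- gram(maps[["2"]])
  expect_equal(as.numeric(v), as.vector(t(G)), tolerance = 1e-9)
  expect_length(v, 16)
})

test_that("multi-window style is the elementwise mean of per-window grams", {
  m <- small_model()
  set.seed(22)
  # stride 32 on a 96 bp sequence -> windows at 0 and 32
  s <- random_dna(96)
  feats <- style_features(m, c(x = s), layer = 3, stride = 32L)
  g1 <- gram(extract_feature_maps(m, one_hot_encode(substr(s, 1, 64)))[["3"]])
  g2 <- gram(extract_feature_maps(m, one_hot_encode(substr(s, 33, 96)))[["3"]])
  expect_equal(as.numeric(feats[1, ]), as.vector(t((g1 + g2) / 2)),
               tolerance = 1e-9)
  expect_equal(unname(attr(feats, "n_windows")["x"]), 2L)
})

test_that("periodic sequences give the same style as any single period", {
  m <- small_model()
  period <- random_dna(32, seed = 23)
  s3 <- strrep(period, 4)                      # 128 bp, windows at 0/32/64
  v_all <- style_features(m, c(p = s3), layer = 2, stride = 32L)
  v_one <- style_features(m, c(p = substr(s3, 1, 64)), layer = 2,
                          stride = 32L)
  expect_equal(v_all, v_one, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("coverage augmentation applies the z-score times style-sd rule", {
  feats <- matrix(c(0, 0, 4, 2, 8, 4), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  st <- coverage_scale_stats(feats, c(0, 10, 20))
  # population z-scores of (0,10,20) are -1.2247, 0, 1.2247
  aug <- augment_features(feats, c(0, 10, 20))
  s <- st$style_sd_mean
  expect_equal(unname(aug[, 3]), c(-1.224745, 0, 1.224745) * s,
               tolerance = 1e-6)
  expect_equal(unname(aug[, 1:2]), unname(feats))

  one <- augment_with_coverage(feats[1, ], 20, st)
  expect_length(one, 3)
  expect_equal(one[3], 1.224745 * s, tolerance = 1e-6)

  # constant coverage contributes nothing
  st0 <- coverage_scale_stats(feats, c(7, 7, 7))
  expect_equal(augment_with_coverage(feats[2, ], 7, st0)[3], 0)
  # degenerate style (s = 0) nullifies the coverage dimension too
  flat <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  aug0 <- augment_features(flat, c(0, 10, 20))
  expect_equal(unname(aug0[, 5]), rep(0, 3))
  expect_error(augment_with_coverage(feats[1, ], -1, st), "negative")
})
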