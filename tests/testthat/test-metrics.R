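test_that("pair counts enumerate the worked examples exactly", {
  truth <- c("s1", "s1", "s2", "s2")              # {a,b | c,d}
  expect_equal(pair_counts(truth, truth),
               list(TP = 2, FN = 0, FP = 0, TN = 4))
  all_in_one <- rep("x", 4)
  expect_equal(pair_counts(truth, all_in_one),
               list(TP = 2, FN = 0, FP = 4, TN = 0))
  expect_equal(pair_counts("a", "b"), list(TP = 0, FN = 0, FP = 0, TN = 0))
  expect_error(pair_counts(1:3, 1:4), "different lengths")
})

test_that("pair-based scores match the O(n^2) pair loop on random labelings", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    truth <- sample(letters[1:4], n, replace = TRUE)
    pred <- sample(1:5, n, replace = TRUE)
    pc <- pair_counts(truth, pred)
    oc <- oracle_pair_counts(truth, pred)
    expect_equal(pc[c("TP", "TN", "FP", "FN")],
                 oc[c("TP", "TN", "FP", "FN")], ignore_attr = TRUE)
    # RI and F from the oracle counts agree with the package functions
    expect_equal(rand_index(truth, pred),
                 (oc$TP + oc$TN) / choose(n, 2))
    f <- if (oc$TP == 0) 0 else {
      rec <- oc$TP / (oc$TP + oc$FN)
      pre <- oc$TP / (oc$TP + oc$FP)
      2 * rec * pre / (rec + pre)
    }
    expect_equal(pair_f_measure(pc), f)
  }
})

test_that("ARI agrees with an independent implementation and fixed points", {
  skip_if_not_installed("mclust")
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(8:40, 1)
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(truth, pred),
                 mclust::adjustedRandIndex(truth, pred), tolerance = 1e-12)
  }
  truth <- rep(c("a", "b"), each = 5)
  expect_equal(adjusted_rand_index(truth, truth), 1)
  expect_equal(adjusted_rand_index(truth, rep("z", 10)), 0)
})

test_that("homogeneity and completeness hit their defining fixed points", {
  truth <- rep(c("a", "b"), each = 4)
  hc <- homogeneity_completeness(truth, truth)
  expect_equal(hc, list(homogeneity = 1, completeness = 1))

  lump <- homogeneity_completeness(truth, rep(1, 8))
  expect_equal(lump, list(homogeneity = 0, completeness = 1))

  # all-singletons: pure bins, and completeness 1 - H(K|C)/H(K)
  # = 1 - log(4)/log(8) = 1/3 under the entropy definitions
  split <- homogeneity_completeness(truth, 1:8)
  expect_equal(split, list(homogeneity = 1, completeness = 1 / 3))

  f <- pair_counts(c("a", "a", "b", "b"), rep(1, 4))
  expect_equal(pair_f_measure(f), 0.5)     # rec = 1, pre = 1/3
})

test_that("all scores are invariant to relabeling either side", {
  set.seed(63)
  truth <- sample(letters[1:3], 40, replace = TRUE)
  pred <- sample(1:4, 40, replace = TRUE)
  relab_t <- c(a = "z", b = "q", c = "m")[truth]
  relab_p <- c(40, 10, 20, 30)[pred]
  s1 <- clustering_scores(truth, pred)
  s2 <- clustering_scores(relab_t, relab_p)
  nm <- c("rand_index", "ari", "homogeneity", "completeness", "f_measure")
  expect_equal(s1[nm], s2[nm])
})

test_that("splitting a predicted bin never decreases homogeneity", {
  # conditioning on a finer partition cannot raise H(C|K), so homogeneity is
  # monotone under refinement; completeness is NOT monotone in general
  # (both H(K|C) and H(K) grow), so only its trade-off from the perfect
  # clustering is asserted below
  set.seed(64)
  for (rep in 1:10) {
    n <- 60
    truth <- sample(1:4, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    before <- homogeneity_completeness(truth, pred)
    pred2 <- pred
    victims <- which(pred == sample(1:3, 1))
    if (length(victims) >= 2) {
      half <- sample(victims, floor(length(victims) / 2))
      pred2[half] <- 99
      after <- homogeneity_completeness(truth, pred2)
      expect_gte(after$homogeneity + 1e-12, before$homogeneity)
    }
  }
  # trade-off: splitting a class-aligned bin keeps bins pure but breaks a
  # class across bins, so homogeneity stays 1 while completeness drops
  truth <- rep(c("a", "b"), each = 10)
  aligned <- rep(1:2, each = 10)
  refined <- c(rep(1, 5), rep(3, 5), rep(2, 10))
  before <- homogeneity_completeness(truth, aligned)
  after <- homogeneity_completeness(truth, refined)
  expect_equal(after$homogeneity, 1)
  expect_lt(after$completeness, before$completeness)
})

test_that("ARI is centered at zero under the permutation null", {
  set.seed(65)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  aris <- replicate(1000, adjusted_rand_index(truth, sample(pred)))
  expect_lt(abs(mean(aris)), 0.01)
})
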