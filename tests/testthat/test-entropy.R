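test_that("ApEn matches the naive template-counting reference", {
  set.seed(11)
  for (i in 1:10) {
    y <- random_test_series(sample(60:150, 1),
                            sample(c("ar1", "white", "mixed"), 1))
    r <- 0.2 * sd(y)
    expect_equal(approximate_entropy(y, m = 2, r_abs = r),
                 oracle_apen(y, 2, r), tolerance = 1e-12)
  }
  expect_equal(approximate_entropy(rep(1, 50), 2, 0.1), 0)
  # alternating series: every continuation is determined, ApEn near 0
  y <- rep(c(1, 2), 150)
  expect_lt(abs(approximate_entropy(y, 1, 0.05) - oracle_apen(y, 1, 0.05)),
            1e-12)
  expect_lt(abs(approximate_entropy(y, 1, 0.05)), 0.01)
  expect_error(approximate_entropy(1:3, m = 2, r_abs = 1), "too short")
  expect_error(approximate_entropy(1:50, m = 2, r_abs = 0), "positive")
})

test_that("SampEn matches the naive reference and handles degeneracy", {
  set.seed(12)
  for (i in 1:10) {
    y <- random_test_series(sample(60:150, 1),
                            sample(c("ar1", "white", "mixed"), 1))
    r <- 0.2 * sd(y)
    expect_equal(as.numeric(sample_entropy(y, 2, r)),
                 as.numeric(oracle_sampen(y, 2, r)), tolerance = 1e-12)
  }
  expect_equal(as.numeric(sample_entropy(rep(3.5, 60), 2, 0.1)), 0)
  # ramp with tolerance below the step size: no template pairs match
  ramp <- as.numeric(1:40)
  v <- sample_entropy(ramp, m = 2, r_abs = 0.5)
  expect_true(isTRUE(attr(v, "degenerate")))
  expect_equal(as.numeric(v), log(38) + log(37))
  expect_true(is.finite(v))
})

test_that("PermEn matches exhaustive ordinal-pattern counting", {
  set.seed(13)
  for (i in 1:10) {
    y <- rnorm(200)
    for (k in 2:3)
      expect_equal(permutation_entropy(y, k = k, tau = 1),
                   oracle_permen(y, k, 1), tolerance = 1e-12)
  }
  # delay > 1 and tie handling agree with the stable-ranking oracle
  y <- sample(rep(1:5, 8))
  expect_equal(permutation_entropy(y, k = 3, tau = 2),
               oracle_permen(y, 3, 2), tolerance = 1e-12)
  expect_equal(permutation_entropy(1:100, k = 4), 0)
  # both k = 2 patterns exactly equally often -> normalized entropy 1
  y <- c(rep(c(1, 2), 200), 1)  # 400 windows: 200 rising, 200 falling
  expect_equal(permutation_entropy(y, k = 2), 1)
  expect_error(permutation_entropy(1:3, k = 4), "too short")
})

test_that("FuzzyEn matches the naive membership-sum reference", {
  set.seed(14)
  for (i in 1:10) {
    y <- random_test_series(sample(60:150, 1),
                            sample(c("ar1", "white", "mixed"), 1))
    p <- 0.2 * sd(y)
    expect_equal(fuzzy_entropy(y, m = 2, n_exp = 2, p_width = p),
                 oracle_fuzzyen(y, 2, 2, p), tolerance = 1e-12)
  }
  expect_equal(fuzzy_entropy(rep(2, 50), 2, 2, 0.1), 0)
  # membership depends on d^n / p: scaling series by c with p scaled by
  # c^n leaves the result unchanged
  y <- rnorm(100)
  expect_equal(fuzzy_entropy(10 * y, 2, 2, 0.3 * 10^2),
               fuzzy_entropy(y, 2, 2, 0.3), tolerance = 1e-10)
})

test_that("LogEn follows its closed form and floor behaviour", {
  expect_equal(log_energy_entropy(c(1, -1, 1, -1)), 0)
  expect_equal(log_energy_entropy(c(exp(1), exp(1))), 4)
  expect_equal(log_energy_entropy(numeric(16) + 0, floor_eps = 1e-12),
               16 * log(1e-12))
  # invariant to sample reordering
  y <- rnorm(100)
  expect_equal(log_energy_entropy(y), log_energy_entropy(rev(y)))
  expect_equal(log_energy_entropy(y), log_energy_entropy(sample(y)))
})

test_that("PermEn is order-sensitive where LogEn is not", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(permutation_entropy(y, k = 3), 0)
  expect_gt(permutation_entropy(c(3, 1, 4, 1, 5, 9, 2, 6), k = 3), 0)
})

test_that("white noise has higher SampEn than a strong AR(1) process", {
  set.seed(15)
  se_white <- se_ar <- numeric(50)
  for (i in 1:50) {
    w <- rnorm(200)
    a <- as.numeric(stats::filter(rnorm(200, sd = sqrt(1 - 0.9^2)),
                                  0.9, method = "recursive"))
    se_white[i] <- sample_entropy(w, 2, 0.2 * sd(w))
    se_ar[i] <- sample_entropy(a, 2, 0.2 * sd(a))
  }
  expect_gt(mean(se_white), mean(se_ar))
})

test_that("feature extraction yields 10 values for pairs, 5 for singles", {
  cfg <- synth_config(n_pairs = 1, length = 256, seed = 2)
  pair <- generate_class_signal("FC", cfg, 1)
  fv <- extract_feature_vector(pair)
  expect_length(fv, 10)
  expect_named(fv, c(paste0(c("ApEn", "SampEn", "PermEn", "FuzzyEn",
                              "LogEn"), "_x"),
                     paste0(c("ApEn", "SampEn", "PermEn", "FuzzyEn",
                              "LogEn"), "_y")))
  single <- pair$x
  expect_length(extract_feature_vector(single), 5)
  # determinism: identical calls, identical vectors
  expect_identical(fv, extract_feature_vector(pair))
})

test_that("tolerance coupling makes the feature path scale-invariant", {
  cfg <- synth_config(n_pairs = 1, length = 256, seed = 4)
  rec <- generate_class_signal("NFC", cfg, 1)
  scaled <- paired_signal(
    eeg_signal(rec$x$samples * 37, fs = rec$x$fs),
    eeg_signal(rec$y$samples * 37, fs = rec$y$fs),
    label = rec$label, source_id = rec$source_id)
  a <- extract_feature_vector(rec)
  b <- extract_feature_vector(scaled)
  # LogEn measures absolute energy and FuzzyEn's width scales linearly
  # while its distances enter to the power n; the hard-threshold entropies
  # and the ordinal one are exactly scale-free
  keep <- grepl("ApEn|SampEn|PermEn", names(a))
  expect_equal(a[keep], b[keep], tolerance = 1e-8)
})
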