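test_that("generator produces the requested structure and roles", {
  for (preset in c("sklearn_small", "sklearn_large")) {
    spec <- generator_preset(preset, n_samples = 400, seed = 11)
    d <- generate_classification(spec)
    expect_equal(dim(d$X), c(400L, spec$n_features))
    tab <- table(d$roles)
    expect_equal(unname(tab[["informative"]]), spec$n_informative)
    expect_equal(unname(tab[["redundant"]]), spec$n_redundant)
    expect_equal(unname(tab[["duplicate"]]), spec$n_duplicate)
    expect_equal(unname(tab[["noise"]]),
                 spec$n_features - spec$n_informative -
                   spec$n_redundant - spec$n_duplicate)
    expect_setequal(unique(d$y), c(0L, 1L))
  }
})

test_that("invalid generator specifications name the offending field", {
  expect_error(generator_spec(n_features = 10, n_informative = 8,
                              n_redundant = 3), "n_features")
  expect_error(generator_spec(flip_fraction = 1), "flip_fraction")
  expect_error(generator_spec(class_separation = 0), "class_separation")
  expect_error(generator_spec(n_samples = 0), "n_samples")
})

test_that("duplicate columns are exact copies and redundant columns lie in the informative span", {
  spec <- generator_spec(n_samples = 300, n_features = 20, n_informative = 6,
                         n_redundant = 4, n_duplicate = 3, seed = 5)
  d <- generate_classification(spec)
  cc <- stats::cor(d$X)
  diag(cc) <- 0
  # every duplicate column correlates exactly 1 with its source
  dup_cols <- which(d$roles == "duplicate")
  for (j in dup_cols) expect_true(any(abs(cc[, j] - 1) < 1e-12))
  # redundant columns: least-squares residual on the informative block ~ 0
  inf <- d$X[, d$roles == "informative"]
  for (j in which(d$roles == "redundant")) {
    res <- stats::lsfit(inf, d$X[, j], intercept = FALSE)$residuals
    expect_lt(max(abs(res)), 1e-8)
  }
})

test_that("a purely informative spec spans full column rank with no noise", {
  d <- generate_classification(generator_spec(
    n_samples = 50, n_features = 2, n_informative = 2, seed = 2))
  expect_equal(qr(d$X)$rank, 2L)
  expect_false(any(d$roles == "noise"))
})

test_that("noise columns are label-independent at large n", {
  d <- generate_classification(generator_preset("sklearn_small",
                                                n_samples = 30000, seed = 3))
  noise_cor <- abs(stats::cor(d$X[, d$roles == "noise"], d$y))
  expect_lt(max(noise_cor), 0.05)
})

test_that("a fixed seed reproduces the dataset bit-identically", {
  s <- generator_spec(n_samples = 200, n_features = 15, n_informative = 5,
                      n_redundant = 2, n_duplicate = 1, seed = 99)
  d1 <- generate_classification(s)
  d2 <- generate_classification(s)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
})

test_that("subsampling preserves columns, respects size limits, and is reproducible", {
  d <- generate_classification(generator_spec(n_samples = 500, seed = 7))
  s <- subsample(d, 10, seed = 1)
  expect_equal(dim(s$X), c(10L, ncol(d$X)))
  expect_identical(s$roles, d$roles)
  expect_identical(subsample(d, 50, seed = 4)$X, subsample(d, 50, seed = 4)$X)
  # n = N without replacement is a row permutation
  full <- subsample(d, nrow(d$X), seed = 2)
  expect_equal(full$X[order(full$X[, 1]), ], d$X[order(d$X[, 1]), ])
  expect_error(subsample(d, nrow(d$X) + 1), "exceeds")
  # bootstrap can exceed N
  expect_equal(nrow(subsample(d, 600, seed = 3, with_replacement = TRUE)$X),
               600L)
})

test_that("single-class subsamples trigger a warning", {
  X <- matrix(rnorm(1000), 500, 2)
  y <- c(rep(0L, 499), 1L)
  d <- klr_dataset(X, y)
  expect_warning(subsample(d, 2, seed = 1), "single class")
})

test_that("nested subsamples are strict subsets and reproducible", {
  d <- generate_classification(generator_spec(n_samples = 100, seed = 8))
  pr <- nested_subsample(d, 5, 10, seed = 1)
  idx <- attr(pr, "indices")
  expect_length(idx$small, 5L)
  expect_true(all(idx$small %in% idx$large))
  expect_lt(length(idx$small), length(idx$large))
  pr2 <- nested_subsample(d, 5, 10, seed = 1)
  expect_identical(attr(pr2, "indices"), idx)
  expect_error(nested_subsample(d, 10, 10), "strictly less")
  # n = N: the large set is the whole dataset
  pr3 <- nested_subsample(d, 2, nrow(d$X), seed = 2)
  expect_setequal(attr(pr3, "indices")$large, seq_len(nrow(d$X)))
})

test_that("truth_overlap matches oracle, pure-noise, and hypergeometric baselines", {
  d <- generate_classification(generator_preset("sklearn_small",
                                                n_samples = 200, seed = 4))
  expect_equal(truth_overlap(ranker_oracle()(d), d), 1.0)
  # ranking that puts all noise columns first
  noise_first <- feature_ranking(as.numeric(d$roles == "noise"),
                                 feature_names = d$feature_names)
  k_noise <- sum(d$roles == "noise")
  expect_equal(truth_overlap(noise_first, d, k = k_noise), 0.0)
  # random rankings: expected overlap = (#relevant)/d by the hypergeometric
  set.seed(10)
  rr <- ranker_random()
  ov <- replicate(300, truth_overlap(rr(d), d))
  expect_equal(mean(ov), sum(d$roles != "noise") / ncol(d$X),
               tolerance = 0.05)
  # roles are required
  d_norole <- klr_dataset(d$X, d$y)
  expect_error(truth_overlap(noise_first, d_norole), "roles")
})
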