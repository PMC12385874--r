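test_that("a root-only tree predicts the training class-1 rate everywhere", {
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2)
  y <- c(rep(1L, 7), rep(0L, 13))
  d <- klr_dataset(X, y)
  stump <- data.frame(feature = NA_integer_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_)
  ens <- bayesianize_trees(list(stump), d)
  expect_equal(predict(ens, c(5, -5)), 7 / 20)
  expect_equal(tree_marginal(ens, c(0, 0), 1), 7 / 20)
})

test_that("a depth-1 stump is annotated with routed counts and leaf rates", {
  # feature 1 <= 0 goes left: 5 rows (3 positive), right: 5 rows (2 positive)
  X <- cbind(c(rep(-1, 5), rep(1, 5)), rnorm(10))
  y <- c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L)
  d <- klr_dataset(X, y)
  stump <- data.frame(feature = c(1L, NA, NA), threshold = c(0, NA, NA),
                      left = c(2L, NA, NA), right = c(3L, NA, NA))
  ens <- bayesianize_trees(list(stump), d)
  nodes <- ens$trees[[1]]
  expect_equal(nodes$n_left[1], 5)
  expect_equal(nodes$n_right[1], 5)
  expect_equal(nodes$prob[2], 0.6)
  expect_equal(nodes$prob[3], 0.4)
  # marginalizing the split feature mixes the leaves 50/50
  expect_equal(tree_marginal(ens, c(-1, 0), 1), 0.5 * 0.6 + 0.5 * 0.4)
  # ordinary prediction still follows the hard path
  expect_equal(predict(ens, c(-1, 0)), 0.6)
})

test_that("routed counts are conserved parent-to-child", {
  set.seed(42)
  d <- generate_classification(generator_spec(n_samples = 300,
                                              n_features = 6,
                                              n_informative = 3, seed = 43))
  rf <- randomForest::randomForest(d$X, factor(d$y), ntree = 5,
                                   keep.inbag = TRUE, nodesize = 10)
  ens <- bayesianize_trees(rf, d)
  for (nodes in ens$trees) {
    for (id in which(!is.na(nodes$feature))) {
      kids <- c(nodes$left[id], nodes$right[id])
      for (side in 1:2) {
        k <- kids[side]
        routed <- if (side == 1) nodes$n_left[id] else nodes$n_right[id]
        if (!is.na(nodes$feature[k])) {
          expect_equal(nodes$n_left[k] + nodes$n_right[k], routed)
        }
      }
    }
    expect_true(all(nodes$prob[is.na(nodes$feature)] >= 0 &
                      nodes$prob[is.na(nodes$feature)] <= 1))
  }
})

test_that("trees that never split on a feature are unchanged by its marginalization", {
  set.seed(44)
  tr <- rand_tree(d = 4, max_depth = 3)
  used <- unique(stats::na.omit(tr$feature))
  unused <- setdiff(1:5, used)[1]
  ens <- new_tree_fixture(list(tr), n_features = 5)
  x <- rnorm(5)
  expect_equal(tree_marginal(ens, x, unused), predict(ens, x))
})

test_that("fractional traversal equals the exhaustive-path oracle", {
  set.seed(45)
  for (rep in 1:25) {
    tr <- rand_tree(d = 4, max_depth = 4)
    ens <- new_tree_fixture(list(tr), n_features = 4)
    x <- rnorm(4)
    i <- sample(4, 1)
    oracle <- brute_force_tree_marginal(tr, x, i)
    expect_equal(tree_marginal(ens, x, i), oracle$value, tolerance = 1e-12)
  }
})

test_that("path weights over consistent leaves sum to one", {
  set.seed(46)
  for (rep in 1:40) {
    tr <- rand_tree(d = 3, max_depth = 4)
    x <- rnorm(3)
    i <- sample(3, 1)
    expect_equal(sum(tree_path_weights(tr, x, i)), 1, tolerance = 1e-12)
  }
})

test_that("structural defects are rejected", {
  bad <- data.frame(feature = c(1L, NA, NA), threshold = c(0, NA, NA),
                    left = c(2L, NA, NA), right = c(3L, NA, NA),
                    n_left = c(0, NA, NA), n_right = c(0, NA, NA),
                    prob = c(NA, 0.5, 0.5))
  d <- make_logit_data(10, c(0, 1), seed = 47)
  expect_error(bayesianize_trees(list(bad), d), "zero routed")
  noprob <- data.frame(feature = NA_integer_, threshold = NA_real_,
                       left = NA_integer_, right = NA_integer_,
                       n_left = NA_real_, n_right = NA_real_, prob = 1.7)
  expect_error(bayesianize_trees(list(noprob), d), "probability")
})

test_that("randomForest ensembles produce probabilities and react to marginalization", {
  set.seed(48)
  d <- generate_classification(generator_spec(n_samples = 400,
                                              n_features = 5,
                                              n_informative = 2, seed = 49))
  rf <- randomForest::randomForest(d$X, factor(d$y), ntree = 20,
                                   keep.inbag = TRUE, nodesize = 20)
  ens <- bayesianize_trees(rf, d)
  p_full <- predict(ens, d$X[1:20, ])
  expect_true(all(p_full >= 0 & p_full <= 1))
  p_marg <- predict(ens, d$X[1:20, ], marginalize = 1)
  expect_true(all(p_marg >= 0 & p_marg <= 1))
  expect_false(all(p_marg == p_full))
})
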