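test_that("the Bernoulli KL divergence matches direct evaluation and is asymmetric", {
  expect_equal(kl_bernoulli(0.3, 0.3), 0)
  # frozen oracle values: p*log(p/q) + (1-p)*log((1-p)/(1-q))
  expect_equal(kl_bernoulli(0.8, 0.6), 0.09151622, tolerance = 1e-6)
  expect_equal(kl_bernoulli(0.6, 0.8), 0.10464963, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(kl_bernoulli(0.8, 0.6),
                                kl_bernoulli(0.6, 0.8))))
  set.seed(51)
  p <- runif(200)
  q <- runif(200)
  expect_true(all(kl_bernoulli(p, q) >= 0))
  expect_true(all(kl_bernoulli(p, p) == 0))
  # boundary values stay finite through clipping
  expect_true(is.finite(kl_bernoulli(0, 1)))
  expect_error(kl_bernoulli(1.2, 0.5), "0, 1")
})

test_that("log-scale KL agrees with the probability-scale formula away from saturation", {
  set.seed(52)
  z <- rnorm(100)
  zh <- rnorm(100)
  expect_equal(klrank:::kl_bernoulli_z(z, zh),
               kl_bernoulli(pnorm(z), pnorm(zh)), tolerance = 1e-9)
  # and keeps resolution where pnorm saturates in double precision
  expect_gt(klrank:::kl_bernoulli_z(12, 10), 0)
})

test_that("features the model ignores have zero relevance everywhere", {
  d <- make_logit_data(200, c(0.1, 1.2, -0.8, 0), seed = 53)
  fit <- bayes_logistic(d)
  fit$theta_map[4] <- 0
  fit$covariance[4, ] <- 0
  fit$covariance[, 4] <- 0
  expect_equal(local_relevance(fit, d$X[3, ], 3), 0)
  expect_equal(global_relevance(fit, d, 3), 0)
  expect_equal(entropy_diff_relevance(fit, d, 3), 0)
  # tree that never splits on the feature
  set.seed(54)
  tr <- rand_tree(d = 2, max_depth = 3)
  ens <- new_tree_fixture(list(tr), n_features = 3)
  expect_equal(local_relevance(ens, rnorm(3), 3), 0)
})

test_that("global relevance is a mean of pointwise relevances", {
  d <- make_logit_data(50, c(0, 1, -1), seed = 55)
  fit <- bayes_logistic(d)
  # single-row dataset: global equals local on that row
  one_row <- d
  one_row$X <- d$X[7, , drop = FALSE]
  one_row$y <- d$y[7]
  expect_equal(global_relevance(fit, one_row, 1),
               local_relevance(fit, d$X[7, ], 1))
  # duplicating every row leaves the mean unchanged
  dd <- klr_dataset(rbind(d$X, d$X), c(d$y, d$y))
  expect_equal(global_relevance(fit, dd, 2), global_relevance(fit, d, 2))
})

test_that("the vectorized linear fast path equals per-row closed-form predictions", {
  d <- make_logit_data(80, c(0.2, 1, -0.6, 0.3), seed = 56)
  fit <- bayes_logistic(d)
  pr <- klrank:::logit_predictive_all(fit, d$X)
  expect_equal(pr$p_full, unname(predict(fit, d$X)))
  for (i in 1:3) {
    expect_equal(pr$p_marg[, i], unname(predict(fit, d$X, marginalize = i)))
  }
  # and the assembled ranking scores match slow global_relevance
  r <- rank_features(fit, d, method = "kl_bayes")
  slow <- vapply(1:3, function(i) global_relevance(fit, d, i), numeric(1))
  expect_equal(sort(ranking_scores_of(r), decreasing = TRUE)[r$rank],
               r$score)
  expect_equal(unname(ranking_scores_of(r)), slow, tolerance = 1e-12)
})

test_that("analytic and Monte-Carlo relevance paths agree for a linear model", {
  # marginalize a weak-weight feature, where mean imputation and full
  # marginalization coincide up to sampling error
  d <- make_logit_data(600, c(0.1, 0.9, -0.05), seed = 57)
  fit <- bayes_logistic(d)
  x <- d$X[9, ]
  p <- predict(fit, x)
  closed <- predict(fit, x, marginalize = 2)
  reps <- vapply(d$X[, 2], function(v) {
    xx <- x
    xx[2] <- v
    predict(fit, xx)
  }, numeric(1))
  mc <- mc_marginal(fit, x, 2, d, draws = nrow(d$X))
  expect_equal(mc, mean(reps))
  expect_lt(abs(kl_bernoulli(p, closed) - kl_bernoulli(p, mc)), 1e-3)
})

test_that("entropy-difference relevance is bounded and paired with the KL score", {
  d <- make_logit_data(100, c(0, 1.5, -0.5), seed = 58)
  fit <- bayes_logistic(d)
  for (i in 1:2) {
    ed <- entropy_diff_relevance(fit, d, i)
    expect_lt(abs(ed), log(2))
    expect_true(is.finite(global_relevance(fit, d, i)))
  }
})

test_that("embedded relevance sorts by absolute weight with deterministic ties", {
  r <- embedded_relevance(c(`(Intercept)` = 3, a = 0.5, b = -2, c = 0))
  expect_equal(r$index, c(2L, 1L, 3L))
  expect_equal(r$feature, c("b", "a", "c"))
  # sign flips do not change the ranking
  r2 <- embedded_relevance(c(`(Intercept)` = 3, a = -0.5, b = 2, c = 0))
  expect_equal(r$index, r2$index)
  # exact ties break by feature index
  r3 <- embedded_relevance(c(a = 1, b = -1, c = 1))
  expect_equal(r3$index, 1:3)
})

test_that("rank_features orders scores, breaks ties by index, and dispatches", {
  d <- make_logit_data(150, c(0, 0, 0, 2), seed = 59)
  fit <- bayes_logistic(d)
  r <- rank_features(fit, d, method = "kl_bayes")
  expect_equal(r$index[1], 3L)  # the only used feature ranks first
  expect_true(all(diff(r$score) <= 0))
  expect_setequal(r$index, seq_len(ncol(d$X)))
  # duplicate columns earn identical scores and adjacent deterministic ranks
  X <- cbind(rnorm(200), rnorm(200))
  X <- cbind(X, X[, 1])
  y <- rbinom(200, 1, plogis(X[, 1]))
  dd <- klr_dataset(X, y)
  rd <- rank_features(bayes_logistic(dd), dd, method = "kl_bayes")
  s <- ranking_scores_of(rd)
  expect_equal(s[1], s[3], tolerance = 1e-10)
  expect_error(rank_features(lm(rnorm(10) ~ 1), d, method = "kl_bayes"),
               "unsupported")
})

test_that("KL and embedded rankings correlate positively on well-sampled data", {
  d <- generate_classification(generator_preset("sklearn_small",
                                                n_samples = 2000, seed = 60))
  rkl <- ranker_kl_bayes()(d)
  remb <- ranker_embedded()(d)
  expect_gt(kendall_corr(rkl, remb), 0)
})
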