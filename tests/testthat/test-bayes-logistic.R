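test_that("null data gives posterior mass around zero weights", {
  set.seed(21)
  X <- matrix(rnorm(4000 * 8), 4000, 8)
  y <- rbinom(4000, 1, 0.5)  # independent of X
  fit <- bayes_logistic(X, y)
  z <- abs(coef(fit)[-1]) / sqrt(diag(vcov(fit))[-1])
  expect_true(all(z < 3))
})

test_that("a known logistic slope is recovered on simulated data", {
  d <- make_logit_data(5000, c(0, 2), seed = 22)
  fit <- bayes_logistic(d, prior_precision = 1e-4)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.1)
})

test_that("an infinitely strong prior shrinks the MAP to zero", {
  d <- make_logit_data(500, c(0.3, 1, -1), seed = 23)
  fit <- bayes_logistic(d, prior_precision = 1e8)
  expect_lt(max(abs(coef(fit)[-1])), 1e-4)
})

test_that("quasi-separated data warn but stay finite", {
  X <- matrix(c(rnorm(50, -8), rnorm(50, 8)), ncol = 1)
  y <- rep(c(0L, 1L), each = 50)
  expect_warning(fit <- bayes_logistic(X, y, prior_precision = 1e-6),
                 "separat")
  expect_true(all(is.finite(coef(fit))))
})

test_that("formula and matrix interfaces agree", {
  d <- make_logit_data(300, c(0, 1, -0.5), seed = 24)
  df <- data.frame(y = d$y, a = d$X[, 1], b = d$X[, 2])
  f1 <- bayes_logistic(y ~ a + b, data = df)
  f2 <- bayes_logistic(d$X, d$y)
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-8)
})

test_that("the probit predictive matches its Monte-Carlo posterior oracle", {
  set.seed(25)
  for (rep in 1:20) {
    p <- sample(2:4, 1)
    theta <- rnorm(p + 1)
    Lam <- rand_psd(p + 1)
    fit <- structure(list(theta_map = theta, covariance = Lam,
                          feature_means = numeric(p),
                          probit_scale = FALSE),
                     class = "bayes_logit")
    x <- rnorm(p)
    mc <- mc_probit_predictive(theta, Lam, x, draws = 20000)
    expect_lt(abs(predict(fit, x) - mc$mean), 3 * mc$se + 1e-8)
  }
})

test_that("delta posterior and zero weights reduce the predictive to its limits", {
  p <- 3
  theta <- c(0.4, 1, -2, 0.5)
  fit0 <- structure(list(theta_map = theta,
                         covariance = matrix(0, 4, 4),
                         feature_means = numeric(p), probit_scale = FALSE),
                    class = "bayes_logit")
  x <- c(0.3, -1, 2)
  expect_equal(predict(fit0, x), pnorm(sum(theta * c(1, x))))
  fitz <- structure(list(theta_map = numeric(4),
                         covariance = rand_psd(4),
                         feature_means = numeric(p), probit_scale = FALSE),
                    class = "bayes_logit")
  expect_equal(predict(fitz, x), 0.5)
})

test_that("mean-imputed marginalization has the stated fixed points", {
  d <- make_logit_data(400, c(0.2, 1, -1, 0.5), seed = 26)
  fit <- bayes_logistic(d)
  x <- d$X[5, ]
  # x_i already at its mean: marginal equals full
  x_at_mean <- x
  x_at_mean[2] <- fit$feature_means[2]
  expect_equal(predict(fit, x_at_mean, marginalize = 2),
               predict(fit, x_at_mean))
  # zero weight on i: marginal equals full for every x
  fit2 <- fit
  fit2$theta_map[4] <- 0
  fit2$covariance[4, ] <- 0
  fit2$covariance[, 4] <- 0
  expect_equal(predict(fit2, d$X, marginalize = 3),
               predict(fit2, d$X))
  expect_error(predict(fit, x[-1]), "columns")
})

test_that("mean imputation approximates full marginalization for weak symmetric features", {
  set.seed(27)
  n <- 2000
  X <- cbind(rnorm(n), rnorm(n, 2, 1.5))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1] + 0.05 * X[, 2]))
  d <- klr_dataset(X, y)
  fit <- bayes_logistic(d)
  x <- X[17, ]
  closed <- predict(fit, x, marginalize = 2)
  # per-replacement spread gives the MC standard error
  reps <- vapply(X[, 2], function(v) {
    xx <- x
    xx[2] <- v
    predict(fit, xx)
  }, numeric(1))
  se <- sd(reps) / sqrt(n)
  expect_lt(abs(closed - mc_marginal(fit, x, 2, d, draws = n)),
            3 * se + 1e-3)
})

test_that("mc_marginal enumerates the dataset exactly when draws cover it", {
  d <- make_logit_data(60, c(0, 1.2, -0.7), seed = 28)
  fit <- bayes_logistic(d)
  x <- d$X[1, ]
  manual <- mean(vapply(d$X[, 1], function(v) {
    xx <- x
    xx[1] <- v
    predict(fit, xx)
  }, numeric(1)))
  expect_equal(mc_marginal(fit, x, 1, d, draws = 60), manual)
  expect_error(mc_marginal(fit, x, 1, d, draws = 0), "draws")
})

test_that("posterior mass and the Bayes-classical predictive gap shrink with n", {
  spec <- function(n) generator_spec(n_samples = n, n_features = 10,
                                     n_informative = 4, n_redundant = 2,
                                     seed = 29)
  holdout <- generate_classification(generator_spec(
    n_samples = 200, n_features = 10, n_informative = 4, n_redundant = 2,
    seed = 30))
  norms <- c()
  gaps <- c()
  for (n in c(100, 1000, 10000)) {
    fit <- bayes_logistic(generate_classification(spec(n)))
    norms <- c(norms, norm(vcov(fit), "F"))
    gaps <- c(gaps, max(abs(predict(fit, holdout$X) -
                              predict(fit, holdout$X, type = "map"))))
  }
  expect_true(all(diff(norms) < 0))
  expect_true(all(diff(gaps) < 0))
})

test_that("probit_scale applies the conventional sigmoid correction", {
  d <- make_logit_data(200, c(0, 1), seed = 31)
  f1 <- bayes_logistic(d, probit_scale = TRUE)
  x <- 1.3
  eta <- coef(f1)[1] + coef(f1)[2] * x
  expect_equal(predict(f1, x, type = "map"),
               unname(pnorm(sqrt(pi / 8) * eta)))
})
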