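#' Kullback-Leibler divergence between two Bernoulli distributions
#'
#' \deqn{KL(p \| \hat p) = p \log\frac{p}{\hat p} +
#'   (1-p)\log\frac{1-p}{1-\hat p}}
#' in natural log (nats).  Inputs are clipped to
#' \eqn{[\epsilon, 1-\epsilon]} so the divergence stays finite at the
#' boundary.
#'
#' @param p,p_hat probabilities in `[0, 1]`; vectorized with recycling.
#' @param clip boundary clipping constant (default `1e-12`).
#' @return Non-negative divergence in nats.
#' @examples
#' kl_bernoulli(0.8, 0.6)
#' @export
kl_bernoulli <- function(p, p_hat, clip = 1e-12) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(p_hat < 0 | p_hat > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  p <- pmin(pmax(p, clip), 1 - clip)
  p_hat <- pmin(pmax(p_hat, clip), 1 - clip)
  pmax(p * log(p / p_hat) + (1 - p) * log((1 - p) / (1 - p_hat)), 0)
}

#' Bernoulli entropy in nats
#'
#' @param p probability vector; clipped as in [kl_bernoulli()].
#' @param clip boundary clipping constant.
#' @return Entropy values in `[0, log(2)]`.
#' @export
bernoulli_entropy <- function(p, clip = 1e-12) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -p * log(p) - (1 - p) * log(1 - p)
}

# Internal dispatcher: full and feature-marginalized predictive
# probabilities for one feature vector, by model family.
#  - bayes_logit: closed-form probit shortcuts
#  - bayes_trees: hard path vs fractional traversal
#  - noise_model: parameter-noise sampling; requires `data` for the
#    Monte-Carlo marginalization of feature i
pred_pair <- function(model, x, i, data = NULL, draws = 500, seed = NULL) {
  if (inherits(model, "bayes_logit")) {
    list(p = predict(model, x),
         p_hat = predict(model, x, marginalize = i))
  } else if (inherits(model, "bayes_trees")) {
    list(p = predict(model, x),
         p_hat = tree_marginal(model, x, i))
  } else if (inherits(model, "noise_model")) {
    if (is.null(data)) {
      stop("noise_model relevance needs `data` to resample feature values")
    }
    if (!is.null(seed)) set.seed(seed)
    list(p = mean(randomize_predict(model, x, draws)),
         p_hat = mc_marginal(model, x, i, data, draws))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

#' Monte-Carlo feature marginalization of the predictive distribution
#'
#' Estimates \eqn{p(y | x_{-i})} by averaging the model's predictive
#' probability over copies of `x` whose `i`-th coordinate is replaced by
#' values of that feature resampled from `data`:
#' \eqn{\frac{1}{|D|}\sum_{x' \in D} p(y | x_{-i}, x'_i)}, subsampled to
#' `draws` rows (all rows, exactly, when `draws >= nrow`).  For a
#' [noise_randomize()] model each evaluation additionally draws a fresh
#' noisy parameter vector.
#'
#' @param model `bayes_logit`, `bayes_trees`, or `noise_model`.
#' @param x a single feature vector.
#' @param i feature index to marginalize.
#' @param data a `klr_data` supplying replacement values.
#' @param draws number of replacement values (`>= 1`).
#' @param seed optional integer seed.
#' @return Probability in `[0, 1]`.
#' @export
mc_marginal <- function(model, x, i, data, draws = 500, seed = NULL) {
  stopifnot(inherits(data, "klr_data"))
  n <- nrow(data$X)
  if (n < 1L) stop("data is empty")
  if (draws < 1) stop("draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  i <- as.integer(i)
  vals <- if (draws >= n) data$X[, i] else data$X[sample.int(n, draws), i]
  Xrep <- matrix(x, length(vals), length(x), byrow = TRUE)
  Xrep[, i] <- vals
  if (inherits(model, "noise_model")) {
    th <- model$base_parameters
    mean(vapply(seq_len(nrow(Xrep)), function(r) {
      eps <- stats::rnorm(length(th), 0, model$noise_sigma)
      model$predictor(Xrep[r, ], th + eps)
    }, numeric(1)))
  } else {
    mean(predict(model, Xrep))
  }
}

#' Pointwise KL relevance of a feature
#'
#' The information lost at a specific input `x` when feature `i` is
#' marginalized out:
#' \eqn{KL\big(p(y|x) \,\|\, p(y|x_{-i})\big)}, computed with the model
#' family's shortcut (probit closed form for `bayes_logit`, fractional
#' traversal for `bayes_trees`, parameter-noise sampling for
#' `noise_model`).
#'
#' @inheritParams mc_marginal
#' @param data training data; required for `noise_model` only.
#' @param clip probability clipping for the KL evaluation.
#' @return Non-negative relevance in nats.
#' @export
local_relevance <- function(model, x, i, data = NULL, draws = 500,
                            seed = NULL, clip = 1e-12) {
  pp <- pred_pair(model, x, i, data = data, draws = draws, seed = seed)
  kl_bernoulli(pp$p, pp$p_hat, clip = clip)
}

#' Global KL relevance of a feature
#'
#' Arithmetic mean of [local_relevance()] over the rows of `data`: the
#' overall relevance score \eqn{rel(i) = E_x\,KL(p(y|x) \| p(y|x_{-i}))}.
#'
#' @inheritParams local_relevance
#' @param data a `klr_data`; rows are both the averaging set and (for
#'   Monte-Carlo marginalization) the replacement pool.
#' @return Non-negative relevance in nats.
#' @export
global_relevance <- function(model, data, i, draws = 500, seed = NULL,
                             clip = 1e-12) {
  stopifnot(inherits(data, "klr_data"))
  if (nrow(data$X) < 1L) stop("data is empty")
  if (inherits(model, "bayes_logit")) {
    # vectorized closed form, evaluated on the probit scale for stability
    pr <- logit_predictive_all(model, data$X)
    return(mean(kl_bernoulli_z(pr$z_full, pr$z_marg[, i])))
  }
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(nrow(data$X)), function(r) {
    local_relevance(model, data$X[r, ], i, data = data, draws = draws,
                    clip = clip)
  }, numeric(1)))
}

#' Entropy-difference relevance
#'
#' The alternative large-sample form of the KL relevance:
#' \eqn{E_x\big[H(p(y|x_{-i})) - H(p(y|x))\big]} with \eqn{H} the
#' Bernoulli entropy in nats.  Unlike [global_relevance()] this quantity
#' can be negative; the two coincide only asymptotically (cross-entropy
#' vs entropy), so both are exposed.
#'
#' @inheritParams global_relevance
#' @return Signed relevance in nats.
#' @export
entropy_diff_relevance <- function(model, data, i, draws = 500, seed = NULL,
                                   clip = 1e-12) {
  stopifnot(inherits(data, "klr_data"))
  if (inherits(model, "bayes_logit")) {
    pr <- logit_predictive_all(model, data$X)
    return(mean(entropy_bernoulli_z(pr$z_marg[, i]) -
                  entropy_bernoulli_z(pr$z_full)))
  }
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(nrow(data$X)), function(r) {
    pp <- pred_pair(model, data$X[r, ], i, data = data, draws = draws)
    bernoulli_entropy(pp$p_hat, clip) - bernoulli_entropy(pp$p, clip)
  }, numeric(1)))
}
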