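#' Feature ranking objects
#'
#' A `feature_ranking` is a data frame with columns `rank`, `feature`,
#' `index` (original column index) and `score`, ordered by decreasing
#' score with ties broken deterministically by feature index.  Attributes
#' `method`, `n_obs` and `provenance` record how it was produced.
#'
#' @param scores numeric score per feature (higher = more relevant).
#' @param feature_names names aligned with `scores`.
#' @param method method tag, e.g. `"kl_bayes"`.
#' @param n_obs number of rows the ranking was computed from.
#' @param provenance optional named list stored as an attribute.
#' @return A `feature_ranking`.
#' @export
feature_ranking <- function(scores, feature_names = NULL,
                            method = "unknown", n_obs = NA_integer_,
                            provenance = list()) {
  d <- length(scores)
  if (is.null(feature_names)) feature_names <- names(scores)
  if (is.null(feature_names)) feature_names <- sprintf("f%03d", seq_len(d))
  ord <- order(-scores, seq_len(d))
  out <- data.frame(rank = seq_len(d), feature = feature_names[ord],
                    index = ord, score = scores[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method = method, n_obs = n_obs, provenance = provenance,
            class = c("feature_ranking", "data.frame"))
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<feature_ranking> method = %s, %d features (n_obs = %s)\n",
              attr(x, "method"), nrow(x), attr(x, "n_obs")))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n")
  invisible(x)
}

#' @export
plot.feature_ranking <- function(x, top = 20L, ...) {
  top <- min(top, nrow(x))
  graphics::barplot(rev(x$score[seq_len(top)]),
                    names.arg = rev(x$feature[seq_len(top)]),
                    horiz = TRUE, las = 1,
                    xlab = sprintf("relevance (%s)", attr(x, "method")), ...)
  invisible(x)
}

# scores in original feature order (inverse of the ranking permutation)
ranking_scores <- function(r) {
  s <- numeric(nrow(r))
  s[r$index] <- r$score
  s
}

#' Embedded relevance: absolute weights of a linear model
#'
#' The classical baseline ranker: score = \eqn{|w_i|}, intercept excluded.
#' Only scale-meaningful on standardized features; [rank_features()] with
#' `method = "embedded"` standardizes internally before fitting the
#' classical model.
#'
#' @param weights named weight vector (with or without an `(Intercept)`
#'   entry) or a `bayes_logit` fit.
#' @return A [feature_ranking] with method tag `"embedded"`.
#' @export
embedded_relevance <- function(weights) {
  if (inherits(weights, "bayes_logit")) weights <- coef(weights)
  w <- weights[setdiff(names(weights), "(Intercept)")]
  if (is.null(names(weights))) w <- weights
  feature_ranking(abs(w), feature_names = names(w), method = "embedded")
}

#' Rank all features of a model on a dataset
#'
#' Scores every feature and assembles a [feature_ranking].
#' Supported methods:
#' \describe{
#'   \item{`kl_bayes`}{mean pointwise KL divergence between the full and
#'     feature-marginalized Bayesian predictive ([global_relevance()]);
#'     works for `bayes_logit`, `bayes_trees` and `noise_model`.}
#'   \item{`entropy_diff`}{mean Bernoulli-entropy difference
#'     ([entropy_diff_relevance()]).}
#'   \item{`embedded`}{\eqn{|w_i|} of a classical (ridge-penalized by
#'     default, see [ranker_embedded()]) logistic regression fit on
#'     internally standardized features; `model` is ignored.}
#'   \item{`shap`}{mean absolute Shapley value of a linear-probit
#'     predictor ([shap_relevance()]); `model` must be a `bayes_logit`.}
#' }
#'
#' @param model fitted model object (ignored for `"embedded"`).
#' @param data a `klr_data`.
#' @param method scoring method tag.
#' @param draws Monte-Carlo draws for sampling-based paths.
#' @param seed optional integer seed for sampling-based paths.
#' @param ... further arguments to the scoring function (e.g.
#'   `permutations` for sampled SHAP).
#' @return A [feature_ranking].
#' @examples
#' d <- generate_classification(generator_spec(n_samples = 400, seed = 2))
#' fit <- bayes_logistic(d)
#' rank_features(fit, d, method = "kl_bayes")
#' @export
rank_features <- function(model, data,
                          method = c("kl_bayes", "entropy_diff",
                                     "embedded", "shap"),
                          draws = 500, seed = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "klr_data"))
  d <- ncol(data$X)
  scores <- switch(method,
    kl_bayes = {
      check_model_supported(model)
      if (inherits(model, "bayes_logit")) {
        pr <- logit_predictive_all(model, data$X)
        colMeans(kl_bernoulli_z(matrix(pr$z_full, nrow(data$X), d),
                                pr$z_marg))
      } else {
        if (!is.null(seed)) set.seed(seed)
        vapply(seq_len(d), function(i) {
          global_relevance(model, data, i, draws = draws)
        }, numeric(1))
      }
    },
    entropy_diff = {
      check_model_supported(model)
      if (!is.null(seed)) set.seed(seed)
      vapply(seq_len(d), function(i) {
        entropy_diff_relevance(model, data, i, draws = draws)
      }, numeric(1))
    },
    embedded = abs(classical_logistic_weights(data)),
    shap = {
      if (!inherits(model, "bayes_logit")) {
        stop("method 'shap' requires a bayes_logit model ",
             "(linear-probit predictor)")
      }
      phi <- shap_values(model, data, seed = seed, ...)
      colMeans(abs(phi))
    }
  )
  feature_ranking(scores, feature_names = data$feature_names,
                  method = method, n_obs = nrow(data$X),
                  provenance = list(seed = seed))
}

check_model_supported <- function(model) {
  if (!inherits(model, c("bayes_logit", "bayes_trees", "noise_model"))) {
    stop("unsupported (method, model) pair: model class ",
         paste(class(model), collapse = "/"))
  }
}

# Classical logistic regression weights on z-scored features; the
# embedded baseline.  `penalized = TRUE` (default) is the ridge-penalized
# point fit, matching the common default configuration of off-the-shelf
# logistic solvers and keeping the weights defined under the exact
# collinearity that duplicate/redundant columns induce; `FALSE` is the
# unpenalized ML fit, whose rank-deficient coefficients (NA) score 0.
classical_logistic_weights <- function(data, penalized = TRUE,
                                       prior_precision = 1) {
  Xs <- scale(data$X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  co <- if (penalized) {
    coef(bayes_logistic(Xs, data$y, prior_precision = prior_precision))[-1L]
  } else {
    suppressWarnings(
      stats::glm.fit(cbind(1, Xs), data$y,
                     family = stats::binomial())$coefficients)[-1L]
  }
  co[!is.finite(co)] <- 0
  stats::setNames(co, data$feature_names)
}

#' Ranker constructors
#'
#' A *ranker* is a function `function(data, model = NULL)` returning a
#' [feature_ranking]; the stability metrics and the benchmark harness are
#' written against this interface.  When `model` is `NULL` the ranker fits
#' its own model on `data`.
#'
#' \describe{
#'   \item{`ranker_kl_bayes()`}{fits a [bayes_logistic()] (or Bayesianizes
#'     a supplied `bayes_logit` / `randomForest` / `bayes_trees` model) and
#'     ranks by mean KL relevance.}
#'   \item{`ranker_embedded()`}{classical logistic \eqn{|w_i|} on
#'     standardized features.}
#'   \item{`ranker_shap()`}{mean absolute Shapley value of the fitted
#'     linear-probit model (permutation-sampled by default).}
#'   \item{`ranker_random()`}{a fresh uniform-random permutation per call
#'     (null baseline).}
#'   \item{`ranker_oracle()`}{ground-truth roles: relevant features first
#'     (requires generated data).}
#' }
#'
#' @param prior_precision prior precision for the internal
#'   [bayes_logistic()] fit.
#' @param permutations permutations for sampled SHAP.
#' @param background_size background rows for SHAP expectations.
#' @return A function `(data, model = NULL) -> feature_ranking`.
#' @name rankers
NULL

#' @rdname rankers
#' @export
ranker_kl_bayes <- function(prior_precision = 1) {
  function(data, model = NULL) {
    if (is.null(model)) {
      model <- bayes_logistic(data, prior_precision = prior_precision)
    } else if (inherits(model, "randomForest")) {
      model <- bayesianize_trees(model, data)
    }
    rank_features(model, data, method = "kl_bayes")
  }
}

#' @rdname rankers
#' @param penalized use the ridge-penalized classical fit for the embedded
#'   baseline (the common solver default; keeps weights defined under
#'   exact collinearity).  `FALSE` uses the unpenalized ML fit.
#' @export
ranker_embedded <- function(penalized = TRUE) {
  function(data, model = NULL) {
    w <- classical_logistic_weights(data, penalized = penalized)
    feature_ranking(abs(w), feature_names = data$feature_names,
                    method = "embedded", n_obs = nrow(data$X))
  }
}

#' @rdname rankers
#' @export
ranker_shap <- function(prior_precision = 1, permutations = 30,
                        background_size = 32) {
  function(data, model = NULL) {
    if (is.null(model) || !inherits(model, "bayes_logit")) {
      model <- bayes_logistic(data, prior_precision = prior_precision)
    }
    rank_features(model, data, method = "shap", mode = "sampled",
                  permutations = permutations,
                  background_size = background_size)
  }
}

#' @rdname rankers
#' @export
ranker_random <- function() {
  function(data, model = NULL) {
    d <- ncol(data$X)
    scores <- stats::setNames(sample(seq_len(d)) / d, data$feature_names)
    feature_ranking(scores, feature_names = data$feature_names,
                    method = "random", n_obs = nrow(data$X))
  }
}

#' @rdname rankers
#' @export
ranker_oracle <- function() {
  function(data, model = NULL) {
    if (is.null(data$roles)) stop("oracle ranker needs ground-truth roles")
    scores <- as.numeric(data$roles != "noise")
    feature_ranking(scores, feature_names = data$feature_names,
                    method = "oracle", n_obs = nrow(data$X))
  }
}
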