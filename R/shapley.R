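#' Shapley-value relevance for linear-probit models
#'
#' Shapley attribution of the classical probit output
#' \eqn{f(x) = \Phi(w \cdot x + b)} of a fitted [bayes_logistic()] model,
#' with conditional expectations taken *interventionally*: out-of-coalition
#' features are replaced by values from background rows drawn from the
#' data, so
#' \eqn{\Delta f(i, S) = E[f | x_{S \cup i}] - E[f | x_S]} is estimated by
#' unconditional replacement.  A feature the model ignores (zero weight)
#' therefore receives Shapley value exactly zero.
#'
#' Exact mode enumerates all \eqn{2^{N}} coalitions with the weights
#' \eqn{|S|!\,(N-|S|-1)!/N!} and is limited to `N <= 14` features; sampled
#' mode averages marginal contributions over random feature permutations,
#' each paired with one background row.
#'
#' `shap_relevance()` returns the global score of one feature: the mean
#' over data rows of the absolute Shapley value.
#'
#' @param model a `bayes_logit` (its MAP weights define the predictor).
#' @param data a `klr_data`; rows are both the explained points and the
#'   background pool.
#' @param i feature index to score.
#' @param mode `"exact"` or `"sampled"`.
#' @param permutations permutations per row in sampled mode.
#' @param background_size background rows used for the interventional
#'   expectations (all rows if fewer).
#' @param seed optional integer seed (sampled mode and background draw).
#' @return `shap_relevance()`: a single non-negative score.
#'   `shap_values()`: an `nrow(data) x n_features` matrix of signed
#'   Shapley values.
#' @examples
#' d <- generate_classification(generator_spec(
#'   n_samples = 60, n_features = 4, n_informative = 2, seed = 3))
#' fit <- bayes_logistic(d)
#' shap_relevance(fit, d, i = 1, mode = "exact")
#' @export
shap_relevance <- function(model, data, i, mode = c("sampled", "exact"),
                           permutations = 200, background_size = 32,
                           seed = NULL) {
  phi <- shap_values(model, data, mode = mode, permutations = permutations,
                     background_size = background_size, seed = seed)
  mean(abs(phi[, i]))
}

#' @rdname shap_relevance
#' @export
shap_values <- function(model, data, mode = c("sampled", "exact"),
                        permutations = 200, background_size = 32,
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bayes_logit"), inherits(data, "klr_data"))
  d <- ncol(data$X)
  if (mode == "exact" && d > 14L) {
    stop("exact mode enumerates 2^N coalitions and is capped at N = 14 ",
         "features (got ", d, "); use mode = \"sampled\"")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$X)
  bg_idx <- if (n <= background_size) seq_len(n) else {
    sample.int(n, background_size)
  }
  B <- data$X[bg_idx, , drop = FALSE]
  w <- model$theta_map[-1L]
  b0 <- model$theta_map[1L]
  base <- drop(B %*% w) + b0               # predictor input per background row
  phi <- matrix(0, n, d)
  for (r in seq_len(n)) {
    delta <- t(w * (data$X[r, ] - t(B)))   # m x d: w_j (x_j - b_j)
    phi[r, ] <- if (mode == "exact") {
      shap_row_exact(base, delta)
    } else {
      shap_row_sampled(base, delta, permutations)
    }
  }
  colnames(phi) <- data$feature_names
  phi
}

# Exact enumeration for one row: v(S) = mean_b Phi(base_b + sum_{j in S}
# delta[b, j]); subset sums built incrementally over bit masks.
shap_row_exact <- function(base, delta) {
  d <- ncol(delta)
  m <- length(base)
  n_mask <- bitwShiftL(1L, d)
  ss <- matrix(0, n_mask, m)
  v <- numeric(n_mask)
  v[1L] <- mean(stats::pnorm(base))
  for (mask in seq_len(n_mask - 1L)) {
    j <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)[1L]
    prev <- mask - bitwShiftL(1L, j - 1L)
    ss[mask + 1L, ] <- ss[prev + 1L, ] + delta[, j]
    v[mask + 1L] <- mean(stats::pnorm(base + ss[mask + 1L, ]))
  }
  sizes <- vapply(0:(n_mask - 1L), bitcount, integer(1))
  wgt <- factorial(0:(d - 1L)) * factorial(d - 1L - (0:(d - 1L))) /
    factorial(d)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    no_i <- which(bitwAnd(0:(n_mask - 1L), bit) == 0L)   # masks S without i
    phi[i] <- sum(wgt[sizes[no_i] + 1L] *
                    (v[no_i + bit] - v[no_i]))
  }
  phi
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# Permutation sampling for one row: each permutation is paired with one
# background row; walking the permutation accumulates the predictor input
# from the background baseline towards f(x), and successive differences
# are unbiased marginal contributions.
shap_row_sampled <- function(base, delta, permutations) {
  d <- ncol(delta)
  m <- length(base)
  phi <- numeric(d)
  for (p in seq_len(permutations)) {
    b <- if (m == 1L) 1L else sample.int(m, 1L)
    perm <- sample.int(d)
    t_cur <- base[b]
    f_cur <- stats::pnorm(t_cur)
    for (j in perm) {
      t_new <- t_cur + delta[b, j]
      f_new <- stats::pnorm(t_new)
      phi[j] <- phi[j] + (f_new - f_cur)
      t_cur <- t_new
      f_cur <- f_new
    }
  }
  phi / permutations
}
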