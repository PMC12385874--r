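# Shared fixtures and independent oracles for the test suite.

# --- random tree builder (valid node tables for the list adapter) ---------
# Builds a random binary decision tree over `d` features with routed-count
# annotations that satisfy the conservation invariant by construction.
rand_tree <- function(d, max_depth = 3L, n_root = 64L) {
  rows <- list()
  add_node <- function(depth, n) {
    id <- length(rows) + 1L
    rows[[id]] <<- list()  # reserve slot
    if (depth >= max_depth || n < 2L || stats::runif(1) < 0.25) {
      rows[[id]] <<- data.frame(feature = NA_integer_, threshold = NA_real_,
                                left = NA_integer_, right = NA_integer_,
                                n_left = NA_real_, n_right = NA_real_,
                                prob = stats::runif(1))
      return(id)
    }
    n_l <- sample.int(n - 1L, 1L)
    left <- add_node(depth + 1L, n_l)
    right <- add_node(depth + 1L, n - n_l)
    rows[[id]] <<- data.frame(feature = sample.int(d, 1L),
                              threshold = stats::rnorm(1),
                              left = left, right = right,
                              n_left = n_l, n_right = n - n_l,
                              prob = NA_real_)
    id
  }
  add_node(0L, n_root)
  do.call(rbind, rows)
}

# wrap pre-annotated node tables as an ensemble (the list adapter skips
# routing when counts and leaf probabilities are already present)
new_tree_fixture <- function(trees, n_features) {
  dummy <- klr_dataset(matrix(0, 2, n_features), c(0L, 1L))
  bayesianize_trees(trees, dummy)
}

# --- exhaustive-path oracle for the fractional tree traversal -------------
# Enumerates every leaf, reconstructs its root path through a parent map,
# and accumulates the path weight: count fraction at nodes splitting on i,
# consistency indicator elsewhere.  Independent of tree_marginal_one's
# recursion.
brute_force_tree_marginal <- function(nodes, x, i) {
  parent <- rep(NA_integer_, nrow(nodes))
  side <- rep(NA_character_, nrow(nodes))
  for (id in seq_len(nrow(nodes))) {
    if (!is.na(nodes$feature[id])) {
      parent[nodes$left[id]] <- id; side[nodes$left[id]] <- "L"
      parent[nodes$right[id]] <- id; side[nodes$right[id]] <- "R"
    }
  }
  leaves <- which(is.na(nodes$feature))
  total <- 0
  weights <- numeric(0)
  for (l in leaves) {
    w <- 1
    id <- l
    while (!is.na(parent[id])) {
      p <- parent[id]
      tot <- nodes$n_left[p] + nodes$n_right[p]
      if (nodes$feature[p] == i) {
        w <- w * if (side[id] == "L") nodes$n_left[p] / tot else
          nodes$n_right[p] / tot
      } else {
        ok <- x[nodes$feature[p]] <= nodes$threshold[p]
        if ((side[id] == "L") != ok) { w <- 0; break }
      }
      id <- p
    }
    if (w > 0) weights <- c(weights, stats::setNames(w, l))
    total <- total + w * nodes$prob[l]
  }
  list(value = total, weights = weights)
}

# --- Monte-Carlo oracle for the Gaussian-posterior probit predictive ------
# Draws parameter vectors from N(theta, Lambda) and averages the probit
# output; returns the estimate and its standard error.
mc_probit_predictive <- function(theta, Lambda, x, draws = 10000L) {
  L <- chol(Lambda + diag(1e-12, nrow(Lambda)))
  Z <- matrix(stats::rnorm(draws * length(theta)), draws)
  W <- Z %*% L + matrix(theta, draws, length(theta), byrow = TRUE)
  vals <- stats::pnorm(drop(W %*% c(1, x)))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(draws))
}

# random symmetric PSD matrix
rand_psd <- function(p, scale = 0.5) {
  A <- matrix(stats::rnorm(p * p, sd = scale), p)
  crossprod(A) / p
}

# small logistic-model dataset with known weights
make_logit_data <- function(n, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(theta) - 1L
  X <- matrix(stats::rnorm(n * d), n, d)
  eta <- theta[1] + drop(X %*% theta[-1])
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  klr_dataset(X, y)
}

# per-feature scores of a ranking, in original column order
ranking_scores_of <- function(r) {
  s <- numeric(nrow(r))
  s[r$index] <- r$score
  s
}

# ranker that always returns the same ordering (index-descending scores)
constant_ranker <- function() {
  function(data, model = NULL) {
    d <- ncol(data$X)
    feature_ranking(rev(seq_len(d)), feature_names = data$feature_names,
                    method = "constant")
  }
}

# cheap model-free ranker: absolute two-sample t statistic per feature
tstat_ranker <- function() {
  function(data, model = NULL) {
    g1 <- data$y == 1L
    s <- vapply(seq_len(ncol(data$X)), function(j) {
      v <- data$X[, j]
      m <- abs(mean(v[g1]) - mean(v[!g1]))
      m / (stats::sd(v) + 1e-12)
    }, numeric(1))
    feature_ranking(s, feature_names = data$feature_names, method = "tstat")
  }
}
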