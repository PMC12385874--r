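#' Labeled classification dataset with optional ground-truth feature roles
#'
#' Container used throughout the package: a numeric feature matrix, a binary
#' 0/1 target, feature names, and (for synthetic data) a role label per
#' column, one of `"informative"`, `"redundant"`, `"duplicate"`, `"noise"`.
#'
#' @param X numeric matrix, one row per example.
#' @param y binary target; anything coercible to two distinct values.
#'   Internally stored as integer 0/1 (the second sorted level is 1).
#' @param feature_names character vector, defaults to `colnames(X)` or
#'   `f01, f02, ...`.
#' @param roles optional character vector of per-column roles.
#' @return An object of class `klr_data`: a list with elements `X`, `y`,
#'   `feature_names`, `roles`.
#' @examples
#' d <- klr_dataset(matrix(rnorm(20), 10, 2), rep(0:1, 5))
#' d
#' @export
klr_dataset <- function(X, y, feature_names = NULL, roles = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) {
    stop("nrow(X) [", nrow(X), "] must equal length(y) [", length(y), "]")
  }
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop("y must take exactly two distinct values, got: ",
         paste(utils::head(lev, 5), collapse = ", "))
  }
  y <- as.integer(y == lev[2L])
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) {
      feature_names <- sprintf("f%02d", seq_len(ncol(X)))
    }
  }
  if (length(feature_names) != ncol(X)) {
    stop("feature_names must have length ncol(X)")
  }
  if (!is.null(roles)) {
    roles <- as.character(roles)
    if (length(roles) != ncol(X)) {
      stop("roles must have length ncol(X) = ", ncol(X))
    }
    bad <- setdiff(unique(roles), c("informative", "redundant", "duplicate", "noise"))
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names, roles = roles),
            class = "klr_data")
}

#' @export
print.klr_data <- function(x, ...) {
  cat(sprintf("<klr_data> %d examples x %d features; class balance %d/%d\n",
              nrow(x$X), ncol(x$X), sum(x$y == 0L), sum(x$y == 1L)))
  if (!is.null(x$roles)) {
    tab <- table(factor(x$roles, levels = c("informative", "redundant",
                                            "duplicate", "noise")))
    cat("  roles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.klr_data <- function(x) dim(x$X)

#' Specification of the synthetic classification generator
#'
#' Bundles and validates the parameters of [generate_classification()].
#' Defaults follow the conventional generator settings: one Gaussian cluster
#' per class at opposite scaled hypercube vertices, class separation 1,
#' 1\% label noise, balanced classes.
#'
#' @param n_samples,n_features positive counts.
#' @param n_informative,n_redundant,n_duplicate counts;
#'   `n_informative + n_redundant + n_duplicate <= n_features`.
#' @param class_separation positive Mahalanobis half-distance between the
#'   two class centroids in the informative subspace.
#' @param flip_fraction label-noise rate in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A validated list of class `generator_spec`.
#' @seealso [generator_preset()] for the two benchmark presets.
#' @export
generator_spec <- function(n_samples = 1000, n_features = 20,
                           n_informative = 5, n_redundant = 0,
                           n_duplicate = 0, class_separation = 1.0,
                           flip_fraction = 0.01, seed = NULL) {
  chk_count <- function(v, name, min = 0L) {
    if (length(v) != 1L || is.na(v) || v < min || v != round(v)) {
      stop("invalid '", name, "': must be an integer >= ", min)
    }
    as.integer(v)
  }
  n_samples <- chk_count(n_samples, "n_samples", 1L)
  n_features <- chk_count(n_features, "n_features", 1L)
  n_informative <- chk_count(n_informative, "n_informative", 1L)
  n_redundant <- chk_count(n_redundant, "n_redundant")
  n_duplicate <- chk_count(n_duplicate, "n_duplicate")
  if (n_informative + n_redundant + n_duplicate > n_features) {
    stop("n_informative + n_redundant + n_duplicate (",
         n_informative + n_redundant + n_duplicate,
         ") exceeds n_features (", n_features, ")")
  }
  if (n_duplicate > 0 && n_informative + n_redundant == 0) {
    stop("n_duplicate requires at least one informative or redundant column")
  }
  if (!is.numeric(class_separation) || class_separation <= 0) {
    stop("invalid 'class_separation': must be > 0")
  }
  if (!is.numeric(flip_fraction) || flip_fraction < 0 || flip_fraction >= 1) {
    stop("invalid 'flip_fraction': must be in [0, 1)")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, n_redundant = n_redundant,
                 n_duplicate = n_duplicate,
                 class_separation = class_separation,
                 flip_fraction = flip_fraction, seed = seed),
            class = "generator_spec")
}

#' Benchmark generator presets
#'
#' Two standard synthetic benchmarks: `"sklearn_small"` (50 features: 15
#' informative, 8 redundant, 3 duplicates, rest Gaussian noise) and
#' `"sklearn_large"` (300 features: 25 informative, 10 redundant, 5
#' duplicates).
#'
#' @param name `"sklearn_small"` or `"sklearn_large"`.
#' @param n_samples number of rows to generate (default 30000).
#' @param ... overrides passed on to [generator_spec()].
#' @return A `generator_spec`.
#' @export
generator_preset <- function(name = c("sklearn_small", "sklearn_large"),
                             n_samples = 30000, ...) {
  name <- match.arg(name)
  if (name == "sklearn_small") {
    generator_spec(n_samples = n_samples, n_features = 50, n_informative = 15,
                   n_redundant = 8, n_duplicate = 3, ...)
  } else {
    generator_spec(n_samples = n_samples, n_features = 300, n_informative = 25,
                   n_redundant = 10, n_duplicate = 5, ...)
  }
}

#' Generate a synthetic classification dataset with known feature roles
#'
#' Informative columns are drawn from one unit-variance Gaussian cluster per
#' class, the two clusters centred at opposite scaled hypercube vertices
#' `(-a, ..., -a)` and `(+a, ..., +a)` with `a = class_separation /
#' sqrt(n_informative)`, so every informative coordinate separates the
#' classes and the Mahalanobis half-distance between the class centroids is
#' `class_separation` regardless of how many informative features there
#' are (the overall difficulty of the problem does not change with the
#' informative count).  Redundant columns are
#' random linear combinations of the informative block (rescaled to unit
#' sample variance); duplicate columns are exact copies of randomly chosen
#' informative or redundant columns; all remaining columns are independent
#' standard Gaussians carrying no label information.  A fraction
#' `flip_fraction` of labels is flipped uniformly at random.
#'
#' Column order is informative, redundant, duplicate, noise; the `roles`
#' field records the role of every column.
#'
#' @param spec a [generator_spec()].
#' @return A [klr_dataset()] with `roles` set.
#' @examples
#' d <- generate_classification(generator_spec(n_samples = 200, seed = 1))
#' table(d$roles)
#' @export
generate_classification <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  k <- spec$n_informative
  n1 <- n %/% 2L
  y <- c(rep(0L, n - n1), rep(1L, n1))
  # per-coordinate offset; Mahalanobis half-distance = class_separation
  a <- spec$class_separation / sqrt(k)
  centroid <- a * (2 * y - 1)  # -a for class 0, +a for class 1
  Xinf <- matrix(stats::rnorm(n * k), n, k) + centroid
  blocks <- list(Xinf)
  roles <- rep("informative", k)
  if (spec$n_redundant > 0) {
    B <- matrix(stats::runif(k * spec$n_redundant, -1, 1), k, spec$n_redundant)
    Xred <- Xinf %*% B
    sds <- apply(Xred, 2, stats::sd)
    sds[sds == 0] <- 1
    Xred <- sweep(Xred, 2, sds, "/")
    blocks <- c(blocks, list(Xred))
    roles <- c(roles, rep("redundant", spec$n_redundant))
  }
  if (spec$n_duplicate > 0) {
    pool <- do.call(cbind, blocks)
    src <- sample.int(ncol(pool), spec$n_duplicate, replace = TRUE)
    blocks <- c(blocks, list(pool[, src, drop = FALSE]))
    roles <- c(roles, rep("duplicate", spec$n_duplicate))
  }
  n_noise <- spec$n_features - length(roles)
  if (n_noise > 0) {
    blocks <- c(blocks, list(matrix(stats::rnorm(n * n_noise), n, n_noise)))
    roles <- c(roles, rep("noise", n_noise))
  }
  X <- do.call(cbind, blocks)
  if (spec$flip_fraction > 0) {
    flip <- stats::runif(n) < spec$flip_fraction
    y[flip] <- 1L - y[flip]
  }
  klr_dataset(X, y, feature_names = sprintf("f%03d", seq_len(ncol(X))),
              roles = roles)
}

#' Subsample rows of a dataset
#'
#' Uniform random subsample, optionally a bootstrap (with replacement).
#' Feature roles are preserved.  A warning is emitted when the subsample
#' contains a single class.
#'
#' @param data a `klr_data`.
#' @param n number of rows to draw (`>= 2`).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param with_replacement draw a bootstrap sample instead.
#' @return A `klr_data` with `n` rows.
#' @export
subsample <- function(data, n, seed = NULL, with_replacement = FALSE) {
  stopifnot(inherits(data, "klr_data"))
  N <- nrow(data$X)
  if (n < 2) stop("n must be >= 2")
  if (!with_replacement && n > N) {
    stop("n (", n, ") exceeds dataset size (", N,
         ") and with_replacement is FALSE")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n, replace = with_replacement)
  out <- data
  out$X <- data$X[idx, , drop = FALSE]
  out$y <- data$y[idx]
  if (length(unique(out$y)) < 2L) {
    warning("subsample contains a single class")
  }
  out
}

#' Nested pair of subsamples
#'
#' Draws a size-`n` subsample `B` without replacement and a size-`m`
#' subsample `A` of `B`'s rows, so the rows of `A` are a strict subset of
#' the rows of `B` (used by the monotonicity stability metric).
#'
#' @param data a `klr_data`.
#' @param m,n sizes with `m < n <= nrow(data$X)`.
#' @param seed optional integer seed.
#' @return A list `list(small = A, large = B)` of two `klr_data` objects;
#'   attribute `"indices"` carries the row indices of each.
#' @export
nested_subsample <- function(data, m, n, seed = NULL) {
  stopifnot(inherits(data, "klr_data"))
  if (m >= n) stop("m (", m, ") must be strictly less than n (", n, ")")
  if (n > nrow(data$X)) stop("n exceeds dataset size")
  if (!is.null(seed)) set.seed(seed)
  idx_n <- sample.int(nrow(data$X), n)
  idx_m <- idx_n[sample.int(n, m)]
  take <- function(idx) {
    out <- data
    out$X <- data$X[idx, , drop = FALSE]
    out$y <- data$y[idx]
    out
  }
  structure(list(small = take(idx_m), large = take(idx_n)),
            indices = list(small = idx_m, large = idx_n))
}

#' Fraction of truly relevant features among the top of a ranking
#'
#' A feature counts as truly relevant when its generator role is
#' informative, redundant, or duplicate.
#'
#' @param ranking a [feature_ranking].
#' @param data a `klr_data` with `roles` present.
#' @param k number of top-ranked features to inspect; defaults to the number
#'   of truly relevant features.
#' @return Fraction in `[0, 1]`.
#' @export
truth_overlap <- function(ranking, data, k = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"), inherits(data, "klr_data"))
  if (is.null(data$roles)) {
    stop("dataset has no ground-truth roles; truth_overlap needs generated data")
  }
  relevant <- data$roles != "noise"
  if (is.null(k)) k <- sum(relevant)
  if (k > ncol(data$X)) stop("k exceeds the number of features")
  top <- ranking$index[seq_len(k)]
  mean(relevant[top])
}
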