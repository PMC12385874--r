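#' Bayesianized decision-tree ensembles
#'
#' Converts a fitted tree ensemble into a form supporting fractional
#' ("soft") path traversal, the tree analogue of marginalizing a feature
#' out of the predictive distribution.  Every internal node is annotated
#' with the number of training rows routed to each child and every leaf
#' with its trained class-1 probability.  When predicting with feature `i`
#' removed, a node splitting on `i` sends the example down *both* branches
#' with weights \eqn{n_{left}/(n_{left}+n_{right})} and
#' \eqn{n_{right}/(n_{left}+n_{right})} (the missing-value device of the
#' C4.5 algorithm); the marginal prediction is the leaf-probability average
#' weighted by the product of branch weights along each consistent path.
#' Ensemble predictions average over trees.
#'
#' `bayesianize_trees()` accepts either a `randomForest` classification
#' fit (fit with `keep.inbag = TRUE` so that each tree is annotated with
#' its own bootstrap rows; otherwise the full training data is routed) or
#' a plain list of node tables following the adapter contract below.
#'
#' @section Tree adapter contract:
#' A tree is a `data.frame` with one row per node (row 1 = root) and
#' columns `feature` (1-based split feature index, `NA` for a leaf),
#' `threshold` (`x[feature] <= threshold` goes left), `left`, `right`
#' (child row indices, `NA` for a leaf), and optionally precomputed
#' `n_left`, `n_right`, `prob`.  Counts and leaf probabilities are
#' (re)computed from the supplied training data unless all are present.
#'
#' @param object fitted ensemble (`randomForest` or list of node tables).
#' @param data a [klr_dataset()] with the training feature space; used to
#'   route rows and compute node counts and leaf class-1 rates.
#' @param ... unused.
#' @return An object of class `bayes_trees`: a list with `trees` (node
#'   tables with `n_left`, `n_right`, `prob` filled in) and `n_features`.
#' @examples
#' d <- generate_classification(generator_spec(n_samples = 300, seed = 1))
#' rf <- randomForest::randomForest(d$X, factor(d$y), ntree = 5,
#'                                  keep.inbag = TRUE)
#' ens <- bayesianize_trees(rf, d)
#' tree_marginal(ens, d$X[1, ], i = 1)
#' @export
bayesianize_trees <- function(object, data, ...) UseMethod("bayesianize_trees")

#' @rdname bayesianize_trees
#' @export
bayesianize_trees.randomForest <- function(object, data, ...) {
  stopifnot(inherits(data, "klr_data"))
  if (object$type != "classification") {
    stop("only classification forests are supported")
  }
  trees <- lapply(seq_len(object$ntree), function(k) {
    tr <- randomForest::getTree(object, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    nodes <- data.frame(
      feature = ifelse(leaf, NA_integer_, tr[, "split var"]),
      threshold = ifelse(leaf, NA_real_, tr[, "split point"]),
      left = ifelse(leaf, NA_integer_, tr[, "left daughter"]),
      right = ifelse(leaf, NA_integer_, tr[, "right daughter"])
    )
    w <- if (!is.null(object$inbag)) object$inbag[, k] else rep(1L, nrow(data$X))
    annotate_tree(nodes, data$X, data$y, w,
                  fallback_prob = ifelse(leaf, tr[, "prediction"] - 1, NA))
  })
  new_bayes_trees(trees, ncol(data$X))
}

#' @rdname bayesianize_trees
#' @export
bayesianize_trees.list <- function(object, data, ...) {
  stopifnot(inherits(data, "klr_data"))
  trees <- lapply(object, function(nodes) {
    nodes <- as.data.frame(nodes)
    req <- c("feature", "threshold", "left", "right")
    if (!all(req %in% names(nodes))) {
      stop("tree adapter: node table must have columns ",
           paste(req, collapse = ", "))
    }
    if (all(c("n_left", "n_right", "prob") %in% names(nodes))) {
      return(validate_tree(nodes))
    }
    annotate_tree(nodes, data$X, data$y, rep(1L, nrow(data$X)))
  })
  new_bayes_trees(trees, ncol(data$X))
}

new_bayes_trees <- function(trees, n_features) {
  structure(list(trees = trees, n_features = n_features),
            class = "bayes_trees")
}

validate_tree <- function(nodes) {
  internal <- !is.na(nodes$feature)
  tot <- nodes$n_left[internal] + nodes$n_right[internal]
  if (any(tot <= 0)) {
    stop("internal node with zero routed training count")
  }
  if (any(nodes$prob[!internal] < 0 | nodes$prob[!internal] > 1, na.rm = TRUE)) {
    stop("leaf probability outside [0, 1]")
  }
  nodes
}

# Route weighted training rows through a node table, filling per-node child
# counts and per-leaf class-1 rates.  `w` is a per-row weight (bootstrap
# multiplicity); fallback_prob supplies leaf probabilities for leaves that
# receive no routed rows (possible when annotating with other data).
annotate_tree <- function(nodes, X, y, w, fallback_prob = NULL) {
  n_nodes <- nrow(nodes)
  cnt <- numeric(n_nodes)
  pos <- numeric(n_nodes)
  route <- function(id, rows) {
    cnt[id] <<- sum(w[rows])
    pos[id] <<- sum(w[rows] * y[rows])
    if (is.na(nodes$feature[id])) return(invisible())
    go_left <- X[rows, nodes$feature[id]] <= nodes$threshold[id]
    route(nodes$left[id], rows[go_left])
    route(nodes$right[id], rows[!go_left])
  }
  route(1L, which(w > 0))
  nodes$n_left <- ifelse(is.na(nodes$feature), NA_real_, cnt[nodes$left])
  nodes$n_right <- ifelse(is.na(nodes$feature), NA_real_, cnt[nodes$right])
  prob <- ifelse(cnt > 0, pos / pmax(cnt, 1), NA_real_)
  prob[!is.na(nodes$feature)] <- NA_real_
  empty <- is.na(nodes$feature) & cnt == 0
  if (any(empty)) {
    if (is.null(fallback_prob) || anyNA(fallback_prob[empty])) {
      stop("leaf with zero routed training count and no fallback probability")
    }
    prob[empty] <- fallback_prob[empty]
  }
  nodes$prob <- prob
  validate_tree(nodes)
}

#' @export
print.bayes_trees <- function(x, ...) {
  sizes <- vapply(x$trees, nrow, integer(1))
  cat(sprintf("<bayes_trees> %d trees (%d-%d nodes), %d features\n",
              length(x$trees), min(sizes), max(sizes), x$n_features))
  invisible(x)
}

# Deterministic single-tree prediction: follow the hard decision path.
tree_predict_one <- function(nodes, x) {
  id <- 1L
  while (!is.na(nodes$feature[id])) {
    id <- if (x[nodes$feature[id]] <= nodes$threshold[id]) {
      nodes$left[id]
    } else {
      nodes$right[id]
    }
  }
  nodes$prob[id]
}

# Fractional traversal: at nodes splitting on feature i take both branches
# with count-proportional weights; elsewhere follow x.
tree_marginal_one <- function(nodes, x, i) {
  rec <- function(id) {
    f <- nodes$feature[id]
    if (is.na(f)) return(nodes$prob[id])
    if (f == i) {
      wl <- nodes$n_left[id] / (nodes$n_left[id] + nodes$n_right[id])
      wl * rec(nodes$left[id]) + (1 - wl) * rec(nodes$right[id])
    } else if (x[f] <= nodes$threshold[id]) {
      rec(nodes$left[id])
    } else {
      rec(nodes$right[id])
    }
  }
  rec(1L)
}

#' @export
predict.bayes_trees <- function(object, newdata, marginalize = NULL, ...) {
  if (inherits(newdata, "klr_data")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " columns; ensemble expects ",
         object$n_features)
  }
  apply(newdata, 1L, function(x) {
    if (is.null(marginalize)) {
      mean(vapply(object$trees, tree_predict_one, numeric(1), x = x))
    } else {
      mean(vapply(object$trees, tree_marginal_one, numeric(1),
                  x = x, i = as.integer(marginalize)))
    }
  })
}

#' Feature-marginalized tree-ensemble prediction
#'
#' The fractional-path predictive \eqn{p(y = 1 | x_{-i})}: in every tree,
#' nodes splitting on feature `i` route the example down both children with
#' count-proportional weights, and the result is
#' \eqn{\sum_{l \in leaves(x_{-i})} p_l \, p(l)} averaged over trees, where
#' \eqn{p(l)} is the product of branch weights along the path to leaf `l`.
#'
#' @param ens a [bayesianize_trees()] ensemble.
#' @param x a single feature vector.
#' @param i feature index to marginalize out.
#' @return Probability in `[0, 1]`.
#' @export
tree_marginal <- function(ens, x, i) {
  stopifnot(inherits(ens, "bayes_trees"))
  if (length(x) != ens$n_features) {
    stop("x has length ", length(x), "; ensemble expects ", ens$n_features)
  }
  i <- as.integer(i)
  if (i < 1L || i > ens$n_features) stop("feature index out of range")
  mean(vapply(ens$trees, tree_marginal_one, numeric(1), x = x, i = i))
}

#' Leaf weights of the fractional traversal
#'
#' Returns, for one tree, the weight \eqn{p(l)} assigned to every leaf of
#' the set consistent with \eqn{x_{-i}}; the weights sum to one.  Mainly a
#' diagnostic / testing aid.
#'
#' @param nodes a node table (one element of `ens$trees`).
#' @param x a single feature vector.
#' @param i feature index being marginalized.
#' @return Named numeric vector: leaf row index -> weight.
#' @export
tree_path_weights <- function(nodes, x, i) {
  out <- new.env(parent = emptyenv())
  rec <- function(id, w) {
    f <- nodes$feature[id]
    if (is.na(f)) {
      key <- as.character(id)
      prev <- if (is.null(out[[key]])) 0 else out[[key]]
      out[[key]] <- prev + w
      return(invisible())
    }
    if (f == i) {
      wl <- nodes$n_left[id] / (nodes$n_left[id] + nodes$n_right[id])
      rec(nodes$left[id], w * wl)
      rec(nodes$right[id], w * (1 - wl))
    } else if (x[f] <= nodes$threshold[id]) {
      rec(nodes$left[id], w)
    } else {
      rec(nodes$right[id], w)
    }
  }
  rec(1L, 1)
  keys <- ls(out)
  stats::setNames(vapply(keys, function(k) out[[k]], numeric(1)), keys)
}
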