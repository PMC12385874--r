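#' Positive-class F1 score
#'
#' @param y true 0/1 labels.
#' @param prob predicted class-1 probabilities.
#' @param threshold classification threshold.
#' @return F1 of the positive class; `NaN` when there are neither positive
#'   truths nor positive predictions.
#' @export
f1_score <- function(y, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NaN)
  2 * tp / denom
}

#' Model adapters for the benchmark harness
#'
#' A harness *model* is a list with elements `fit(X, y) -> object`,
#' `predict_prob(object, X) -> probabilities` and a `tag`, constructed
#' with `klr_model()`.  Two constructors are shipped:
#' `model_bayes_logistic()` (deterministic ridge-penalized logistic MAP,
#' natively rankable by the KL method) and `model_random_forest()`
#' (classification forest, Bayesianized by fractional path traversal).
#' Any classifier can be plugged in through `klr_model()`.
#'
#' @param fit,predict_prob,tag adapter components.
#' @param prior_precision,ntree hyperparameters stored in the adapter.
#' @return A list of class `klr_model`.
#' @export
klr_model <- function(fit, predict_prob, tag) {
  stopifnot(is.function(fit), is.function(predict_prob),
            is.character(tag), length(tag) == 1L)
  structure(list(fit = fit, predict_prob = predict_prob, tag = tag),
            class = "klr_model")
}

#' @rdname klr_model
#' @export
model_bayes_logistic <- function(prior_precision = 1) {
  klr_model(
    fit = function(X, y) bayes_logistic(X, y, prior_precision = prior_precision),
    predict_prob = function(object, X) predict(object, X),
    tag = "bayes_logistic"
  )
}

#' @rdname klr_model
#' @export
model_random_forest <- function(ntree = 100) {
  klr_model(
    fit = function(X, y) {
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = ntree, keep.inbag = TRUE)
    },
    predict_prob = function(object, X) {
      unname(stats::predict(object, X, type = "prob")[, "1"])
    },
    tag = "random_forest"
  )
}

# deterministic per-cell seed derivation, kept below 2^31
derive_seed <- function(master, ...) {
  k <- c(...)
  s <- as.double(master %% 2147483647L)
  for (v in k) {
    s <- (s * 48271 + as.double(v)) %% 2147483647
  }
  as.integer(s)
}

#' Feature-selection quality-improvement experiment
#'
#' The five-step benchmark run for every combination of train size, top-n
#' and ranker: (1) hold out a validation fraction and draw the train set
#' without replacement from the remainder (bootstrapping only if the
#' requested size exceeds what is available); (2) fit the model and record
#' the positive-class F1 on the validation set; (3) rank features with the
#' trained model and the train data; (4) refit the same-hyperparameter
#' model on the top-n features only and record its validation F1;
#' (5) record the ratio of the two F1 scores.  Each cell is repeated
#' `repetitions` times with derived seeds.
#'
#' @param data a `klr_data`.
#' @param model a [klr_model()] adapter.
#' @param rankers named list of ranker functions (see [rankers]).
#' @param train_sizes vector of training-set sizes.
#' @param top_n_grid vector of feature counts to keep.
#' @param repetitions repetitions per cell.
#' @param validation_fraction held-out fraction in `(0, 1)`.
#' @param seed master seed; every repetition derives its own.
#' @return A `benchmark_result` data frame with one row per
#'   (ranker, train size, top n, repetition): columns `ranker`,
#'   `train_size`, `top_n`, `rep`, `f1_baseline`, `f1_filtered`, `ratio`
#'   (`NaN` when the baseline F1 is 0 or undefined).
#' @export
run_quality_experiment <- function(data, model, rankers,
                                   train_sizes = c(10, 100, 1000),
                                   top_n_grid = c(1, 3, 5, 7, 9, 12),
                                   repetitions = 30,
                                   validation_fraction = 0.2,
                                   seed = 1) {
  stopifnot(inherits(data, "klr_data"), inherits(model, "klr_model"))
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  if (is.null(names(rankers)) || any(names(rankers) == "")) {
    stop("rankers must be a named list")
  }
  N <- nrow(data$X)
  d <- ncol(data$X)
  if (any(top_n_grid > d)) stop("top_n_grid exceeds the number of features")
  rows <- list()
  for (ts in train_sizes) {
    for (rep in seq_len(repetitions)) {
      set.seed(derive_seed(seed, which(train_sizes == ts), rep))
      n_val <- max(2L, round(validation_fraction * N))
      val_idx <- sample.int(N, n_val)
      pool <- setdiff(seq_len(N), val_idx)
      train_idx <- if (ts <= length(pool)) {
        sample(pool, ts)
      } else {
        sample(pool, ts, replace = TRUE)  # bootstrap fallback
      }
      stopifnot(length(intersect(unique(train_idx), val_idx)) == 0L)
      Xtr <- data$X[train_idx, , drop = FALSE]
      ytr <- data$y[train_idx]
      Xval <- data$X[val_idx, , drop = FALSE]
      yval <- data$y[val_idx]
      if (length(unique(ytr)) < 2L) next
      fitted <- model$fit(Xtr, ytr)
      f1_base <- f1_score(yval, model$predict_prob(fitted, Xval))
      train_data <- klr_dataset(Xtr, ytr, feature_names = data$feature_names,
                                roles = data$roles)
      for (rk in names(rankers)) {
        ranking <- tryCatch(rankers[[rk]](train_data, fitted),
                            error = function(e) NULL)
        if (is.null(ranking)) {
          rows[[length(rows) + 1L]] <- data.frame(
            ranker = rk, train_size = ts, top_n = NA_integer_, rep = rep,
            f1_baseline = f1_base, f1_filtered = NA_real_, ratio = NA_real_,
            skipped = TRUE)
          next
        }
        for (top_n in top_n_grid) {
          keep <- sort(ranking$index[seq_len(top_n)])
          refit <- model$fit(Xtr[, keep, drop = FALSE], ytr)
          f1_filt <- f1_score(yval,
                              model$predict_prob(refit, Xval[, keep, drop = FALSE]))
          ratio <- if (!is.finite(f1_base) || f1_base == 0) NaN else {
            f1_filt / f1_base
          }
          rows[[length(rows) + 1L]] <- data.frame(
            ranker = rk, train_size = ts, top_n = top_n, rep = rep,
            f1_baseline = f1_base, f1_filtered = f1_filt, ratio = ratio,
            skipped = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model_tag") <- model$tag
  attr(out, "seed") <- seed
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Order rankers within each benchmark cell
#'
#' Aggregates a [run_quality_experiment()] result to mean F1 ratios per
#' (train size, top n) cell and orders the rankers within each cell by
#' decreasing mean ratio, ties broken alphabetically (and flagged).
#' Cells with an undefined ratio (`NaN`) are excluded from the means, with
#' the excluded count reported.
#'
#' @param res a `benchmark_result`.
#' @return Data frame with columns `train_size`, `top_n`, `ranker`,
#'   `mean_ratio`, `n_used`, `n_dropped`, `position`, `tied`.
#' @export
rank_methods_per_cell <- function(res) {
  stopifnot(inherits(res, "benchmark_result"))
  res <- res[!res$skipped & !is.na(res$top_n), , drop = FALSE]
  cells <- unique(res[, c("train_size", "top_n")])
  rows <- list()
  for (c_ in seq_len(nrow(cells))) {
    sub <- res[res$train_size == cells$train_size[c_] &
                 res$top_n == cells$top_n[c_], , drop = FALSE]
    agg <- vapply(split(sub$ratio, sub$ranker), function(v) {
      c(mean(v[is.finite(v)]), sum(is.finite(v)), sum(!is.finite(v)))
    }, numeric(3))
    ord <- order(-agg[1, ], colnames(agg))
    mr <- agg[1, ord]
    rows[[c_]] <- data.frame(
      train_size = cells$train_size[c_], top_n = cells$top_n[c_],
      ranker = colnames(agg)[ord], mean_ratio = mr,
      n_used = agg[2, ord], n_dropped = agg[3, ord],
      position = seq_along(ord),
      tied = duplicated(round(mr, 12)) | duplicated(round(mr, 12),
                                                    fromLast = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truth-recovery curve of a ranker on synthetic data
#'
#' For each dataset size, generates `reps` independent datasets from
#' `spec`, ranks their features, and records the percent of truly relevant
#' features (informative + redundant + duplicate) among the top-k of the
#' ranking, with k equal to the number of truly relevant features.
#'
#' The conventional estimation protocol averages this percent over 100
#' generated datasets per size; `se_mean_100` reports the run-to-run
#' standard deviation such a 100-dataset mean would have, estimated from
#' the per-dataset spread as `sd_percent / sqrt(100)`.
#'
#' @param ranker a ranker function (see [rankers]).
#' @param spec a [generator_spec()] (its `n_samples`/`seed` are ignored;
#'   sizes come from `size_grid` and seeds are derived from `seed`).
#' @param size_grid vector of dataset sizes.
#' @param reps generated datasets per size (`>= 2`).
#' @param seed master seed.
#' @return Data frame with one row per size: `size`, `mean_percent`,
#'   `sd_percent` (per-dataset), `se_mean_100`, `reps`.
#' @export
truth_recovery_curve <- function(ranker, spec, size_grid, reps = 30,
                                 seed = 1) {
  stopifnot(inherits(spec, "generator_spec"), is.function(ranker))
  if (reps < 2) stop("reps must be >= 2")
  rows <- lapply(seq_along(size_grid), function(si) {
    n <- size_grid[si]
    pct <- vapply(seq_len(reps), function(rep) {
      sp <- spec
      sp$n_samples <- as.integer(n)
      sp$seed <- derive_seed(seed, si, rep)
      d <- generate_classification(sp)
      set.seed(derive_seed(seed, si, rep, 7L))
      100 * truth_overlap(ranker(d), d)
    }, numeric(1))
    data.frame(size = n, mean_percent = mean(pct),
               sd_percent = stats::sd(pct),
               se_mean_100 = stats::sd(pct) / sqrt(100),
               reps = reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}
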