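#' Kendall rank correlation between two feature rankings
#'
#' Tau-b (tie-corrected), computed on the per-feature scores so that tied
#' scores — e.g. duplicate columns — are handled correctly.  Both rankings
#' must cover the same feature set.
#'
#' @param r1,r2 [feature_ranking] objects over identical feature sets.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' a <- feature_ranking(c(4, 3, 2, 1))
#' b <- feature_ranking(c(4, 3, 1, 2))
#' kendall_corr(a, b)  # 0.6667
#' @export
kendall_corr <- function(r1, r2) {
  stopifnot(inherits(r1, "feature_ranking"), inherits(r2, "feature_ranking"))
  if (nrow(r1) != nrow(r2) ||
      !setequal(r1$feature, r2$feature)) {
    stop("rankings cover different feature sets")
  }
  stats::cor(ranking_scores(r1), ranking_scores(r2), method = "kendall")
}

# Draw a subsample guaranteed (up to `retries` redraws) to contain both
# classes; counts the redraws it needed.
draw_two_class <- function(data, n, retries = 20L) {
  for (t in 0:retries) {
    s <- suppressWarnings(subsample(data, n))
    if (length(unique(s$y)) == 2L) {
      return(list(sample = s, retries = t))
    }
  }
  list(sample = NULL, retries = retries)
}

stability_entry <- function(metric, n, taus, reps, retries, seed) {
  taus <- taus[is.finite(taus)]
  q <- stats::quantile(taus, c(0.25, 0.75), names = FALSE, type = 7)
  out <- data.frame(metric = metric, n = n, mean = mean(taus),
                    q25 = q[1], q75 = q[2], n_corr = length(taus),
                    reps = reps, retries = retries)
  class(out) <- c("stability_report", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Ranking stability metrics
#'
#' Monte-Carlo estimates of three stability measures of a ranker, all
#' under the Kendall tau-b correlation:
#' \describe{
#'   \item{self-consistency `SC(n)`}{expected correlation between rankings
#'     from an *independent* pair of subsamples of sizes `m < n`.}
#'   \item{monotonicity `M(n)`}{the nested variant: the size-`m` subsample
#'     is drawn from within the size-`n` one, measuring how much the
#'     ranking changes when the data are extended.}
#'   \item{mutual consistency}{expected correlation between two different
#'     rankers applied to the identical size-`n` subsample.}
#' }
#' Each repetition draws fresh subsamples (redrawn, up to 20 times, if a
#' draw contains a single class), ranks them, and records the correlation;
#' the mean and the 25th/75th percentiles over all `reps * length(m_grid)`
#' correlations are returned.
#'
#' @param ranker,ranker_1,ranker_2 ranker functions
#'   `(data, model = NULL) -> feature_ranking` (see [rankers]).
#' @param data a `klr_data`.
#' @param n larger subsample size (`<= nrow`).
#' @param m_grid smaller sizes; default `{n/10, n/4, n/2}` (minimum 10).
#' @param reps repetitions per `m` (`>= 2`); 100 matches the conventional
#'   estimation protocol.
#' @param seed optional integer seed for the whole procedure.
#' @return A one-row `stability_report` data frame with columns `metric`,
#'   `n`, `mean`, `q25`, `q75`, `n_corr`, `reps`, `retries`.
#' @export
self_consistency <- function(ranker, data, n, m_grid = NULL, reps = 25,
                             seed = NULL) {
  pair_stability("self_consistency", ranker, data, n, m_grid, reps, seed,
                 nested = FALSE)
}

#' @rdname self_consistency
#' @export
monotonicity <- function(ranker, data, n, m_grid = NULL, reps = 25,
                         seed = NULL) {
  pair_stability("monotonicity", ranker, data, n, m_grid, reps, seed,
                 nested = TRUE)
}

pair_stability <- function(metric, ranker, data, n, m_grid, reps, seed,
                           nested) {
  stopifnot(inherits(data, "klr_data"), is.function(ranker))
  if (n > nrow(data$X)) stop("n exceeds dataset size")
  if (reps < 2) stop("reps must be >= 2")
  if (is.null(m_grid)) {
    m_grid <- unique(pmax(10L, as.integer(round(n * c(0.1, 0.25, 0.5)))))
  }
  if (any(m_grid >= n)) stop("every m in m_grid must be < n")
  if (any(m_grid < 2)) stop("every m in m_grid must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  taus <- numeric(0)
  total_retries <- 0L
  for (rep in seq_len(reps)) {
    for (m in m_grid) {
      if (nested) {
        pr <- nested_subsample(data, m, n)
        small <- pr$small
        large <- pr$large
        # nested draws can still be single-class; redraw as a pair
        t <- 0L
        while ((length(unique(small$y)) < 2L ||
                length(unique(large$y)) < 2L) && t < 20L) {
          pr <- nested_subsample(data, m, n)
          small <- pr$small
          large <- pr$large
          t <- t + 1L
        }
        total_retries <- total_retries + t
        if (length(unique(small$y)) < 2L) next
      } else {
        ds <- draw_two_class(data, m)
        dl <- draw_two_class(data, n)
        total_retries <- total_retries + ds$retries + dl$retries
        if (is.null(ds$sample) || is.null(dl$sample)) next
        small <- ds$sample
        large <- dl$sample
      }
      taus <- c(taus, kendall_corr(ranker(small), ranker(large)))
    }
  }
  stability_entry(metric, n, taus, reps, total_retries, seed)
}

#' @rdname self_consistency
#' @export
mutual_consistency <- function(ranker_1, ranker_2, data, n, reps = 25,
                               seed = NULL) {
  stopifnot(inherits(data, "klr_data"),
            is.function(ranker_1), is.function(ranker_2))
  if (n > nrow(data$X)) stop("n exceeds dataset size")
  if (reps < 2) stop("reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  taus <- numeric(0)
  total_retries <- 0L
  for (rep in seq_len(reps)) {
    dr <- draw_two_class(data, n)
    total_retries <- total_retries + dr$retries
    if (is.null(dr$sample)) next
    taus <- c(taus, kendall_corr(ranker_1(dr$sample), ranker_2(dr$sample)))
  }
  stability_entry("mutual_consistency", n, taus, reps, total_retries, seed)
}

#' Stability report over a grid of sample sizes
#'
#' Convenience wrapper evaluating [self_consistency()] and/or
#' [monotonicity()] over a grid of `n`, returning a tidy data frame (one
#' row per metric and size) suitable for plotting stability-vs-sample-size
#' curves.
#'
#' @inheritParams self_consistency
#' @param n_grid vector of subsample sizes.
#' @param metrics subset of `c("self_consistency", "monotonicity")`.
#' @return A `stability_report` data frame.
#' @export
stability_report <- function(ranker, data, n_grid,
                             metrics = c("self_consistency", "monotonicity"),
                             m_grid = NULL, reps = 25, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (n in n_grid) {
    for (metric in metrics) {
      fn <- if (metric == "self_consistency") self_consistency else monotonicity
      rows[[length(rows) + 1L]] <- fn(ranker, data, n, m_grid = m_grid,
                                      reps = reps, seed = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stability_report", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
plot.stability_report <- function(x, ...) {
  metrics <- unique(x$metric)
  graphics::plot(NULL, xlim = range(x$n), ylim = c(-1, 1), log = "x",
                 xlab = "subsample size n", ylab = "Kendall tau", ...)
  for (k in seq_along(metrics)) {
    sub <- x[x$metric == metrics[k], ]
    sub <- sub[order(sub$n), ]
    graphics::lines(sub$n, sub$mean, type = "b", col = k, pch = 16)
    graphics::segments(sub$n, sub$q25, sub$n, sub$q75, col = k)
  }
  graphics::legend("bottomright", legend = metrics, col = seq_along(metrics),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
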