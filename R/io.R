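#' Read a tabular classification dataset from CSV
#'
#' Expects a header row, a binary target column, and numeric feature
#' columns.  String/factor columns are deterministically one-hot encoded
#' (one indicator per sorted category, reference level dropped).  Rows
#' containing missing values are dropped with a message.  A sidecar JSON
#' file `<path>.roles.json` mapping feature name to generator role is read
#' if present.
#'
#' @param path CSV file path.
#' @param target name of the target column (default `"target"`).
#' @return A [klr_dataset()].
#' @export
load_dataset <- function(path, target = "target") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  if (!target %in% names(df)) {
    stop("target column '", target, "' not found; columns are: ",
         paste(utils::head(names(df), 10), collapse = ", "))
  }
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message("dropped ", sum(!keep), " row(s) with missing values")
    df <- df[keep, , drop = FALSE]
  }
  y <- df[[target]]
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop("target '", target, "' must be binary; found values: ",
         paste(utils::head(lev, 6), collapse = ", "))
  }
  feats <- df[setdiff(names(df), target)]
  feats <- encode_categoricals(feats)
  roles <- NULL
  sidecar <- paste0(path, ".roles.json")
  if (file.exists(sidecar)) {
    role_map <- unlist(jsonlite::read_json(sidecar))
    roles <- unname(role_map[colnames(feats)])
  }
  klr_dataset(as.matrix(feats), y, feature_names = colnames(feats),
              roles = roles)
}

#' One-hot encode non-numeric columns of a data frame
#'
#' Deterministic encoding: for each character/factor/logical column one
#' 0/1 indicator per sorted category except the first (reference) level,
#' named `<column>=<category>`.  Numeric columns pass through unchanged.
#'
#' @param df a data frame of feature columns.
#' @return A numeric data frame.
#' @export
encode_categoricals <- function(df) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out <- data.frame(v)
      names(out) <- nm
      return(out)
    }
    v <- as.character(v)
    levs <- sort(unique(v))
    if (length(levs) < 2L) {
      out <- data.frame(rep(0, length(v)))
      names(out) <- nm
      return(out)
    }
    out <- as.data.frame(lapply(levs[-1L], function(l) as.integer(v == l)))
    names(out) <- paste0(nm, "=", levs[-1L])
    out
  })
  do.call(cbind, cols)
}

#' Write a dataset to CSV (plus an optional role sidecar)
#'
#' Inverse of [load_dataset()]: feature columns under their names, the
#' target in a column named `target`, and — when roles are present — a
#' sidecar JSON `<path>.roles.json` mapping feature name to role.
#'
#' @param data a `klr_data`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "klr_data"))
  df <- as.data.frame(data$X)
  df$target <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(data$roles)) {
    jsonlite::write_json(as.list(stats::setNames(data$roles,
                                                 data$feature_names)),
                         paste0(path, ".roles.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write / read a feature ranking
#'
#' TSV: columns `rank`, `feature`, `index`, `score`, `method`.
#' JSON: the same records plus a provenance block (method, `n_obs`, seed
#' and any extra provenance recorded on the ranking); round-trips
#' losslessly through [read_ranking()].
#'
#' @param ranking a [feature_ranking].
#' @param path output path; format chosen by extension (`.tsv` or
#'   `.json`).
#' @return `path`, invisibly (`write_ranking`); a `feature_ranking`
#'   (`read_ranking`).
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (grepl("\\.json$", path)) {
    payload <- list(
      provenance = c(list(method = attr(ranking, "method"),
                          n_obs = attr(ranking, "n_obs")),
                     attr(ranking, "provenance")),
      ranking = as.data.frame(ranking)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- as.data.frame(ranking)
    df$method <- attr(ranking, "method")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (grepl("\\.json$", path)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- payload$ranking
    prov <- payload$provenance
    scores <- numeric(nrow(df))
    scores[df$index] <- df$score
    names(scores)[df$index] <- df$feature
    feature_ranking(scores, method = prov$method,
                    n_obs = if (is.null(prov$n_obs)) NA_integer_ else prov$n_obs,
                    provenance = prov[setdiff(names(prov),
                                              c("method", "n_obs"))])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    scores <- numeric(nrow(df))
    scores[df$index] <- df$score
    names(scores)[df$index] <- df$feature
    feature_ranking(scores, method = df$method[1L], n_obs = NA_integer_)
  }
}

#' Serialize a stability report
#'
#' Tidy CSV (`metric`, `n`, `mean`, `q25`, `q75`, `n_corr`, `reps`,
#' `retries`) or JSON.
#'
#' @param report a `stability_report`.
#' @param path output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the full ranking pipeline from a configuration
#'
#' Loads or generates a dataset, fits and Bayesianizes the requested model
#' family, computes the KL feature ranking, and writes `ranking.tsv` and
#' `ranking.json` (with full provenance) into the output directory.
#' Repeated runs with the same configuration produce byte-identical
#' output.
#'
#' @param config named list (or path to a YAML/JSON file) with fields:
#'   `input` (CSV path) *or* `generator` (`"sklearn_small"` /
#'   `"sklearn_large"`); `target` (default `"target"`); `model`
#'   (`"bayes_logistic"` or `"random_forest"`); `n_samples` (generator
#'   only, default 30000); `prior_precision` (default 1); `ntree`
#'   (default 100); `seed` (default 1); `out_dir` (default `"."`).
#' @return Named character vector of written file paths, invisibly.
#' @export
rank_command <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen) {
    stop("exactly one of 'input' (CSV path) or 'generator' (preset name) ",
         "must be given")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  model_tag <- if (is.null(config$model)) "bayes_logistic" else config$model
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  data <- if (has_input) {
    load_dataset(config$input,
                 target = if (is.null(config$target)) "target" else config$target)
  } else {
    n <- if (is.null(config$n_samples)) 30000L else as.integer(config$n_samples)
    generate_classification(generator_preset(config$generator,
                                             n_samples = n, seed = seed))
  }
  set.seed(seed)
  if (model_tag == "bayes_logistic") {
    pp <- if (is.null(config$prior_precision)) 1 else config$prior_precision
    model <- bayes_logistic(data, prior_precision = pp)
  } else if (model_tag == "random_forest") {
    ntree <- if (is.null(config$ntree)) 100L else as.integer(config$ntree)
    rf <- randomForest::randomForest(data$X, factor(data$y),
                                     ntree = ntree, keep.inbag = TRUE)
    model <- bayesianize_trees(rf, data)
  } else {
    stop("unknown model tag: ", model_tag)
  }
  ranking <- rank_features(model, data, method = "kl_bayes")
  attr(ranking, "provenance") <- list(
    seed = seed, model = model_tag,
    source = if (has_input) config$input else config$generator,
    package_version = as.character(utils::packageVersion("klrank")))
  paths <- c(tsv = file.path(out_dir, "ranking.tsv"),
             json = file.path(out_dir, "ranking.json"))
  write_ranking(ranking, paths[["tsv"]])
  write_ranking(ranking, paths[["json"]])
  invisible(paths)
}
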