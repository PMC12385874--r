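#' Bayesianize an additive-parameter model with Gaussian parameter noise
#'
#' Generic randomization route: given a trained parameter vector
#' \eqn{\hat\theta} and a deterministic predictor \eqn{f(x, \theta)}
#' returning a class-1 probability, predictions are turned into a
#' distribution by evaluating \eqn{f(x, \hat\theta + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2 I)}.  By the Taylor expansion
#' of the moments, the induced bias in the mean prediction is
#' \eqn{O(\sigma_\epsilon^2)} while the prediction spread scales linearly
#' with \eqn{\sigma_\epsilon}, so a small noise scale (default
#' \eqn{10^{-2}}) perturbs the model without leaving its trained regime.
#'
#' @param parameters trained flat parameter vector \eqn{\hat\theta}.
#' @param predictor function `(x, theta) -> probability in [0,1]`, pure and
#'   deterministic; `x` is a single feature vector.
#' @param noise_sigma noise standard deviation \eqn{\sigma_\epsilon > 0}.
#' @return An object of class `noise_model`.
#' @examples
#' f <- function(x, th) plogis(th[1] + sum(th[-1] * x))
#' m <- noise_randomize(c(0, 1, -2), f)
#' randomize_predict(m, c(0.5, 0.1), draws = 5, seed = 1)
#' @export
noise_randomize <- function(parameters, predictor, noise_sigma = 1e-2) {
  if (!is.numeric(parameters) || !length(parameters)) {
    stop("parameters must be a non-empty numeric vector")
  }
  if (!is.function(predictor)) stop("predictor must be a function(x, theta)")
  if (!is.numeric(noise_sigma) || noise_sigma <= 0) {
    stop("noise_sigma must be > 0")
  }
  structure(list(base_parameters = as.numeric(parameters),
                 predictor = predictor, noise_sigma = noise_sigma),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d parameters, sigma_eps = %g\n",
              length(x$base_parameters), x$noise_sigma))
  invisible(x)
}

#' Sample noise-randomized predictions
#'
#' Evaluates the predictor at `draws` independent noisy parameter vectors
#' \eqn{\hat\theta + \epsilon_k}.
#'
#' @param model a [noise_randomize()] model.
#' @param x a single feature vector.
#' @param draws number of evaluations (`>= 2`).
#' @param seed optional integer seed.
#' @return Numeric vector of `draws` probabilities.
#' @export
randomize_predict <- function(model, x, draws = 100, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  if (draws < 2) stop("draws must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  th <- model$base_parameters
  vapply(seq_len(draws), function(k) {
    eps <- stats::rnorm(length(th), 0, model$noise_sigma)
    model$predictor(x, th + eps)
  }, numeric(1))
}

#' @export
predict.noise_model <- function(object, newdata, draws = 200, seed = NULL,
                                ...) {
  if (inherits(newdata, "klr_data")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (!is.null(seed)) set.seed(seed)
  apply(newdata, 1L, function(x) mean(randomize_predict(object, x, draws)))
}
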