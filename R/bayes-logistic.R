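#' Bayesian logistic regression via the Laplace approximation
#'
#' Fits a logistic regression with an isotropic Gaussian prior on the
#' non-intercept weights and approximates the parameter posterior by a
#' Gaussian \eqn{q(w) = N(\theta_{MAP}, \Lambda)} centred at the penalized
#' maximum (the MAP estimate) with covariance equal to the inverse Hessian
#' of the negative log-posterior at the mode.  The Bayesian predictive
#' distribution is then available in closed form through the probit
#' approximation \eqn{\sigma(a) \approx \Phi(a)}:
#' \deqn{p(y = 1 | x) = \Phi\left(\frac{\theta_{MAP} \cdot x}
#'   {\sqrt{1 + x^\top \Lambda x}}\right).}
#'
#' The prior keeps the optimum finite under (quasi-)complete separation; a
#' warning is emitted when the fit approaches separation.
#'
#' @param x feature matrix, a formula, or a [klr_dataset()].
#' @param y binary 0/1 target (matrix interface only).
#' @param prior_precision precision (inverse variance) of the Gaussian prior
#'   on each non-intercept weight; the intercept is effectively unpenalized.
#' @param probit_scale apply the conventional \eqn{\sqrt{\pi/8}} input
#'   scaling to the probit approximation of the sigmoid.  Off by default:
#'   the predictive formula above is used exactly as written.
#' @param maxit,tol Newton iteration controls.
#' @param ... passed between methods.
#' @return An object of class `bayes_logit` with components
#'   `theta_map` (named weight vector including `(Intercept)`),
#'   `covariance` (the Laplace posterior covariance \eqn{\Lambda}),
#'   `feature_means` (training column means, used to build the
#'   mean-imputed vector for feature marginalization), `prior_precision`,
#'   `n_obs`, `converged`.
#' @examples
#' d <- generate_classification(generator_spec(n_samples = 500, seed = 1))
#' fit <- bayes_logistic(d)
#' head(coef(fit))
#' @export
bayes_logistic <- function(x, ...) UseMethod("bayes_logistic")

#' @rdname bayes_logistic
#' @export
bayes_logistic.klr_data <- function(x, prior_precision = 1, ...) {
  bayes_logistic.default(x$X, x$y, prior_precision = prior_precision, ...)
}

#' @rdname bayes_logistic
#' @param data data frame for the formula interface.
#' @export
bayes_logistic.formula <- function(x, data, prior_precision = 1, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  fit <- bayes_logistic.default(mm, y, prior_precision = prior_precision, ...)
  fit$call <- match.call()
  fit
}

#' @rdname bayes_logistic
#' @export
bayes_logistic.default <- function(x, y, prior_precision = 1,
                                   probit_scale = FALSE,
                                   maxit = 100, tol = 1e-8, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("y must contain exactly two classes")
  y <- as.numeric(y == lev[2L])
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (prior_precision <= 0) stop("prior_precision must be > 0")
  n <- nrow(X)
  d <- ncol(X)
  Xa <- cbind(1, X)
  # near-zero precision on the intercept keeps the Hessian invertible
  # without materially penalizing it
  pen <- c(1e-8, rep(prior_precision, d))

  beta <- numeric(d + 1L)
  logpost <- function(b) {
    eta <- drop(Xa %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * sum(pen * b^2)
  }
  obj <- logpost(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(Xa, y - mu)) - pen * beta
    if (max(abs(grad)) < tol * max(1, n / 100)) {
      converged <- TRUE
      break
    }
    H <- crossprod(Xa, Xa * w)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # step halving guards the Newton update
    s <- 1
    repeat {
      cand <- beta + s * step
      val <- logpost(cand)
      if (val >= obj - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- cand
    obj <- val
  }
  eta <- drop(Xa %*% beta)
  if (max(abs(eta)) > 25) {
    warning("fitted log-odds exceed 25: data are (quasi-)separated; ",
            "the Gaussian prior keeps the MAP finite")
  }
  mu <- stats::plogis(eta)
  H <- crossprod(Xa, Xa * (mu * (1 - mu)))
  diag(H) <- diag(H) + pen
  covariance <- tryCatch(chol2inv(chol(H)), error = function(e) {
    diag(H) <- diag(H) + 1e-8 * mean(diag(H))
    chol2inv(chol(H))
  })
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- sprintf("f%02d", seq_len(d))
  names(beta) <- c("(Intercept)", fnames)
  dimnames(covariance) <- list(names(beta), names(beta))
  structure(list(theta_map = beta, covariance = covariance,
                 feature_means = stats::setNames(colMeans(X), fnames),
                 prior_precision = prior_precision,
                 probit_scale = probit_scale,
                 n_obs = n, converged = converged, levels = lev,
                 call = match.call()),
            class = "bayes_logit")
}

#' @export
print.bayes_logit <- function(x, ...) {
  cat(sprintf(
    "<bayes_logit> Laplace-approximate Bayesian logistic regression\n"))
  cat(sprintf("  %d features, %d observations, prior precision %g\n",
              length(x$theta_map) - 1L, x$n_obs, x$prior_precision))
  cat(sprintf("  ||theta_MAP|| = %.4g, tr(Lambda) = %.4g\n",
              sqrt(sum(x$theta_map^2)), sum(diag(x$covariance))))
  invisible(x)
}

#' @export
coef.bayes_logit <- function(object, ...) object$theta_map

#' @export
vcov.bayes_logit <- function(object, ...) object$covariance

#' @export
summary.bayes_logit <- function(object, ...) {
  sdv <- sqrt(diag(object$covariance))
  out <- data.frame(estimate = object$theta_map, posterior_sd = sdv,
                    z = object$theta_map / sdv)
  structure(list(coefficients = out, n_obs = object$n_obs,
                 prior_precision = object$prior_precision),
            class = "summary.bayes_logit")
}

#' @export
print.summary.bayes_logit <- function(x, ...) {
  cat("Laplace-approximate Bayesian logistic regression\n")
  cat(sprintf("n = %d, prior precision = %g\n\n", x$n_obs, x$prior_precision))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Internal: coerce predict input to a plain feature matrix
as_feature_matrix <- function(object, newdata) {
  if (inherits(newdata, "klr_data")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  d <- length(object$theta_map) - 1L
  if (ncol(newdata) != d) {
    stop("newdata has ", ncol(newdata), " columns; model expects ", d)
  }
  newdata
}

# Internal: probit input scaling factor
probit_lambda <- function(object) {
  if (isTRUE(object$probit_scale)) sqrt(pi / 8) else 1
}

#' Predictive distribution of a Bayesian logistic regression
#'
#' `type = "response"` returns the Bayesian probit predictive
#' \eqn{\Phi(\theta_{MAP} \cdot x / \sqrt{1 + x^\top \Lambda x})};
#' `type = "map"` the classical plug-in probit output
#' \eqn{\Phi(\theta_{MAP} \cdot x)} (the large-sample limit of the
#' predictive); `type = "link"` the linear predictor.  With `marginalize = i`
#' the prediction is evaluated at the mean-imputed vector \eqn{\hat x}
#' (coordinate `i` replaced by its training mean), the closed-form
#' feature-marginalized predictive.
#'
#' @param object a `bayes_logit`.
#' @param newdata matrix, numeric vector (one row), or `klr_data`.
#' @param type `"response"`, `"map"`, or `"link"`.
#' @param marginalize optional feature index (1-based, intercept excluded)
#'   to marginalize out by mean imputation.
#' @param ... unused.
#' @return Numeric vector of probabilities (or linear predictors).
#' @export
predict.bayes_logit <- function(object, newdata,
                                type = c("response", "map", "link"),
                                marginalize = NULL, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(object, newdata)
  if (!is.null(marginalize)) {
    i <- as.integer(marginalize)
    if (length(i) != 1L || i < 1L || i > ncol(X)) {
      stop("marginalize must be a single feature index in 1..", ncol(X))
    }
    X[, i] <- object$feature_means[i]
  }
  Xa <- cbind(1, X)
  eta <- drop(Xa %*% object$theta_map)
  if (type == "link") return(eta)
  lam <- probit_lambda(object)
  if (type == "map") return(stats::pnorm(lam * eta))
  s2 <- rowSums((Xa %*% object$covariance) * Xa)
  stats::pnorm(lam * eta / sqrt(1 + lam^2 * s2))
}

# Internal fast path used by the ranking code: full predictive for every
# row plus the marginalized predictive for every (row, feature) pair,
# computed with rank-one updates of the linear predictor and the posterior
# quadratic form (replacing x_i by its mean shifts x by d_i e_i, so
#   eta_hat = eta + d_i theta_i,
#   s2_hat  = s2 + 2 d_i (Lambda x)_i + d_i^2 Lambda_ii).
logit_predictive_all <- function(object, X) {
  X <- as_feature_matrix(object, X)
  d <- ncol(X)
  Xa <- cbind(1, X)
  theta <- object$theta_map
  Lam <- object$covariance
  lam <- probit_lambda(object)
  eta <- drop(Xa %*% theta)
  XL <- Xa %*% Lam                      # n x (d+1), row r = Lambda %*% x_r
  s2 <- rowSums(XL * Xa)
  p_full <- stats::pnorm(lam * eta / sqrt(1 + lam^2 * s2))
  Dm <- matrix(object$feature_means, nrow(X), d, byrow = TRUE) - X  # d_i per row
  eta_hat <- eta + sweep(Dm, 2, theta[-1L], "*")
  diagL <- diag(Lam)[-1L]
  s2_hat <- s2 + 2 * Dm * XL[, -1L, drop = FALSE] +
    sweep(Dm^2, 2, diagL, "*")
  z_marg <- lam * eta_hat / sqrt(1 + lam^2 * s2_hat)
  list(p_full = p_full, p_marg = stats::pnorm(z_marg),
       z_full = lam * eta / sqrt(1 + lam^2 * s2), z_marg = z_marg)
}

# KL between Bernoulli(pnorm(z)) and Bernoulli(pnorm(z_hat)) computed on
# the log scale, so saturated predictive probabilities (|z| large, where
# pnorm rounds to 0 or 1 in double precision) retain their relative
# ordering instead of collapsing to a clipped divergence of zero.
kl_bernoulli_z <- function(z, z_hat) {
  lp <- stats::pnorm(z, log.p = TRUE)
  lq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  lph <- stats::pnorm(z_hat, log.p = TRUE)
  lqh <- stats::pnorm(z_hat, lower.tail = FALSE, log.p = TRUE)
  pmax(exp(lp) * (lp - lph) + exp(lq) * (lq - lqh), 0)
}

# Bernoulli entropy of pnorm(z), log-scale-stable
entropy_bernoulli_z <- function(z) {
  lp <- stats::pnorm(z, log.p = TRUE)
  lq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  -(exp(lp) * lp + exp(lq) * lq)
}
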