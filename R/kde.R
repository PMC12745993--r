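# Weighted Gaussian kernel density estimation on the 2-D embedding.
#
# The estimator is p(x) = 1/(n * b1 * b2) * sum_i w_i * K2((x - x_i)/b),
# with K2 the radially symmetric bivariate standard Gaussian. Every staging
# decision uses either ratios (p >= 0.1 * max p) or comparisons between two
# models with identically normalized weights, so the normalizing constant
# only has to be applied consistently.

#' Scott bandwidth factor
#'
#' The automated bandwidth rule `n^(-1/(4 + d))` for a sample of size `n`
#' in `d` dimensions. By default this factor multiplies the per-axis sample
#' standard deviation (the usual implementation convention); set
#' `kde$raw_bandwidth = TRUE` in the configuration to use the bare factor.
#'
#' @param n sample size (>= 1).
#' @param dx spatial dimension (2 for the embedding plane).
#' @return the bandwidth factor.
#' @export
scott_bandwidth <- function(n, dx = 2) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a count >= 1")
  if (dx < 1) stop("dx must be >= 1")
  n^(-1 / (4 + dx))
}

#' Build a weighted density model on 2-D support points
#'
#' @param support n x 2 matrix of support coordinates (the embedding).
#' @param weights n non-negative weights; need not sum to 1 and are used
#'   exactly as given.
#' @param raw_bandwidth if `FALSE` (default) the Scott factor is scaled by
#'   each axis' sample standard deviation; if `TRUE` the literal factor is
#'   used on both axes.
#' @return a `wkde_model` with fields `support`, `weights`, `bw` (length-2
#'   per-axis bandwidths), `n_points`.
#' @export
wkde_model <- function(support, weights, raw_bandwidth = FALSE) {
  support <- as.matrix(support)
  stopifnot(ncol(support) == 2L, all(is.finite(support)))
  n <- nrow(support)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("one weight per support point required")
  if (any(weights < 0) || anyNA(weights)) {
    stop("weights must be non-negative and finite")
  }
  b <- scott_bandwidth(n, 2)
  if (raw_bandwidth || n < 2L) {
    bw <- c(b, b)
  } else {
    sds <- apply(support, 2L, stats::sd)
    sds[!is.finite(sds) | sds <= 0] <- 1
    bw <- b * sds
  }
  structure(list(support = support, weights = weights, bw = bw,
                 n_points = n),
            class = "wkde_model")
}

#' Evaluate a weighted kernel density estimate
#'
#' @param model a [wkde_model()].
#' @param queries m x 2 matrix of evaluation points (a vector of length 2
#'   is accepted for a single point).
#' @return numeric vector of m density values.
#' @export
evaluate_density <- function(model, queries) {
  stopifnot(inherits(model, "wkde_model"))
  if (model$n_points < 1L) stop("empty support")
  if (is.null(dim(queries))) queries <- matrix(queries, ncol = 2L)
  queries <- as.matrix(queries)
  stopifnot(ncol(queries) == 2L)
  dx <- outer(queries[, 1L], model$support[, 1L], "-") / model$bw[1L]
  dy <- outer(queries[, 2L], model$support[, 2L], "-") / model$bw[2L]
  K <- exp(-0.5 * (dx * dx + dy * dy))
  as.vector(K %*% model$weights) /
    (2 * pi * model$n_points * model$bw[1L] * model$bw[2L])
}

#' Fit a Gaussian by moments
#'
#' Sample mean and population standard deviation (divisor n). Degenerate
#' (constant) inputs get a floor of 1e-6 on sigma with a warning, so the
#' downstream CDF weighting stays defined.
#'
#' @param values numeric vector with at least 2 elements.
#' @return list with `mu` and `sigma`, class `gaussian_params`.
#' @export
gaussian_fit <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values to fit a Gaussian")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma < 1e-6) {
    warning("degenerate (near-constant) sample; sigma floored at 1e-6")
    sigma <- 1e-6
  }
  structure(list(mu = mu, sigma = sigma), class = "gaussian_params")
}

#' Gaussian cumulative distribution function
#'
#' `F(x; mu, sigma)` through the error-function closed form,
#' `0.5 * (1 + erf((x - mu)/(sigma * sqrt(2))))`.
#'
#' @param x numeric vector of evaluation points.
#' @param params a `gaussian_params` from [gaussian_fit()].
#' @return values in `[0, 1]`.
#' @export
gaussian_cdf <- function(x, params) {
  stopifnot(inherits(params, "gaussian_params"), params$sigma > 0)
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  0.5 * (1 + erf((x - params$mu) / (params$sigma * sqrt(2))))
}
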