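#' Beta distribution shape parameters
#'
#' Light container for the two shape parameters of a beta distribution.
#' Both must be strictly positive.
#'
#' @param alpha,beta Strictly positive shape parameters.
#' @return An object of class `beta_params`, a named list with elements
#'   `alpha` and `beta`.
#' @examples
#' beta_params(2, 5)
#' @export
beta_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("beta shape parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(alpha = %g, beta = %g)\n", x$alpha, x$beta))
  invisible(x)
}

check_unit_interval <- function(x, what = "x") {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' Beta density and cumulative distribution
#'
#' `beta_pdf()` evaluates the beta density x^(alpha-1) (1-x)^(beta-1) /
#' B(alpha, beta).  At the interval endpoints the density may be infinite
#' (x = 0 with alpha < 1, x = 1 with beta < 1); it is returned as `Inf`
#' rather than raising, so callers that never evaluate there (the fit's
#' E-step handles boundary points by an explicit rule) stay total.
#' `beta_cdf()` is the regularized incomplete beta function.
#'
#' @param x Numeric vector of values in `[0, 1]`.
#' @param p A [beta_params()] object.
#' @param log Logical; return the log density?
#' @return Numeric vector of densities (possibly `Inf`) or probabilities.
#' @examples
#' beta_pdf(0.25, beta_params(2, 2))  # 6 * 0.25 * 0.75 = 1.125
#' beta_cdf(0.5, beta_params(2, 1))   # x^2 at 0.5 = 0.25
#' @export
beta_pdf <- function(x, p, log = FALSE) {
  stopifnot(inherits(p, "beta_params"))
  check_unit_interval(x)
  stats::dbeta(x, p$alpha, p$beta, log = log)
}

#' @rdname beta_pdf
#' @export
beta_cdf <- function(x, p) {
  stopifnot(inherits(p, "beta_params"))
  check_unit_interval(x)
  stats::pbeta(x, p$alpha, p$beta)
}

#' Convert between beta parameters and (mean, variance)
#'
#' A beta distribution with shapes (alpha, beta) has mean
#' mu = alpha / (alpha + beta) and variance
#' sigma^2 = mu (1 - mu) / (phi + 1), where phi = alpha + beta is the
#' precision.  The inverse map -- the method of moments estimator when fed
#' sample moments -- is phi = mu (1 - mu) / sigma^2 - 1, alpha = mu phi,
#' beta = (1 - mu) phi, defined whenever 0 < sigma^2 < mu (1 - mu).
#'
#' @param p A [beta_params()] object.
#' @param mean Mean in the open interval (0, 1).
#' @param variance Positive variance, strictly below `mean * (1 - mean)`.
#' @return `params_to_moments()`: a list with `mean` and `variance`;
#'   `moments_to_params()`: a [beta_params()] object.
#' @examples
#' params_to_moments(beta_params(3, 12))      # mean 0.2, variance 0.01
#' moments_to_params(0.2, 0.01)               # Beta(3, 12)
#' @export
params_to_moments <- function(p) {
  stopifnot(inherits(p, "beta_params"))
  mu <- p$alpha / (p$alpha + p$beta)
  list(mean = mu, variance = mu * (1 - mu) / (p$alpha + p$beta + 1))
}

#' @rdname params_to_moments
#' @export
moments_to_params <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1) {
    stop("mean must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0) {
    stop("variance must be strictly positive", call. = FALSE)
  }
  if (variance >= mean * (1 - mean)) {
    stop("over-dispersed moments: variance must be below mean * (1 - mean)",
         call. = FALSE)
  }
  phi <- mean * (1 - mean) / variance - 1
  beta_params(mean * phi, (1 - mean) * phi)
}
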