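#' Beta mixture model
#'
#' A finite mixture of beta distributions: mixture coefficients `weights`
#' (a probability simplex) and per-component shape vectors `alpha`, `beta`.
#' Components are stored in canonical order of ascending component mean
#' unless `sort = FALSE` (used internally during fitting, where component
#' identity must stay stable across iterations).
#'
#' @param weights Nonnegative numeric vector summing to 1.
#' @param alpha,beta Strictly positive shape vectors, same length as
#'   `weights`.
#' @param sort Reorder components by ascending mean? Default `TRUE`.
#' @return An object of class `beta_mixture` with fields `c` (component
#'   count), `weights`, `alpha`, `beta`.
#' @examples
#' beta_mixture(c(0.5, 0.5), alpha = c(1, 5), beta = c(5, 1))
#' @export
beta_mixture <- function(weights, alpha, beta, sort = TRUE) {
  k <- length(weights)
  if (k < 1L || length(alpha) != k || length(beta) != k) {
    stop("weights, alpha and beta must have equal positive length",
         call. = FALSE)
  }
  if (anyNA(weights) || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (anyNA(alpha) || anyNA(beta) || any(alpha <= 0) || any(beta <= 0)) {
    stop("component shape parameters must be strictly positive",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  if (sort) {
    ord <- order(alpha / (alpha + beta))
    weights <- weights[ord]
    alpha <- alpha[ord]
    beta <- beta[ord]
  }
  structure(
    list(c = k, weights = as.numeric(weights),
         alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "beta_mixture"
  )
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("Beta mixture with %d component(s):\n", x$c))
  mu <- x$alpha / (x$alpha + x$beta)
  for (j in seq_len(x$c)) {
    cat(sprintf("  [%d] pi = %.4f  alpha = %.4f  beta = %.4f  (mean %.4f)\n",
                j, x$weights[j], x$alpha[j], x$beta[j], mu[j]))
  }
  invisible(x)
}

component_means <- function(model) model$alpha / (model$alpha + model$beta)

#' Mixture density and cumulative distribution
#'
#' @param x Numeric vector in `[0, 1]`.
#' @param model A [beta_mixture()] object.
#' @return Numeric vector: the weighted sum of component densities
#'   (`mixture_pdf`) or component cdfs (`mixture_cdf`).
#' @examples
#' m <- beta_mixture(c(0.3, 0.7), alpha = c(1, 2), beta = c(1, 1))
#' mixture_cdf(0.5, m)  # 0.3 * 0.5 + 0.7 * 0.25
#' @export
mixture_cdf <- function(x, model) {
  stopifnot(inherits(model, "beta_mixture"))
  check_unit_interval(x)
  out <- numeric(length(x))
  for (j in seq_len(model$c)) {
    out <- out + model$weights[j] * stats::pbeta(x, model$alpha[j], model$beta[j])
  }
  out
}

#' @rdname mixture_cdf
#' @export
mixture_pdf <- function(x, model) {
  stopifnot(inherits(model, "beta_mixture"))
  check_unit_interval(x)
  out <- numeric(length(x))
  for (j in seq_len(model$c)) {
    out <- out + model$weights[j] * stats::dbeta(x, model$alpha[j], model$beta[j])
  }
  out
}

#' Components responsible for boundary observations
#'
#' Observations exactly at 0 (resp. 1) are assigned full responsibility to
#' a single component: for x = 0 the component with the smallest alpha
#' (ties broken by the largest beta), because small alpha concentrates
#' density at 0; for x = 1 the component with the smallest beta (ties by
#' largest alpha).  Any remaining tie is broken by the lowest index.
#'
#' @param model A [beta_mixture()] object.
#' @return Integer vector `c(j0, j1)`: the component index taking the
#'   x = 0 observations and the one taking the x = 1 observations.
#' @export
boundary_components <- function(model) {
  stopifnot(inherits(model, "beta_mixture"))
  cand0 <- which(model$alpha == min(model$alpha))
  j0 <- cand0[which.max(model$beta[cand0])]
  cand1 <- which(model$beta == min(model$beta))
  j1 <- cand1[which.max(model$alpha[cand1])]
  c(j0 = j0, j1 = j1)
}
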