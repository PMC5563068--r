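#' Fitting configuration
#'
#' Tunables for the iterated method of moments.  `tol` is the relative
#' change threshold applied to every free parameter (all alpha_j, beta_j
#' and pi_j); the fit stops when every parameter's relative change in one
#' iteration falls below it.  `mean_clamp` and `variance_floor` regularize
#' degenerate responsibility-weighted moments before they are mapped to
#' shape parameters: the weighted mean is clamped into
#' `[mean_clamp, 1 - mean_clamp]` and the weighted variance is floored at
#' `variance_floor` and capped just below `mean * (1 - mean)` so the
#' moment map stays defined.  These guards only affect components whose
#' weighted sample collapses (for example a component owning a single
#' point); non-degenerate fits are untouched.
#'
#' @param tol Relative-change convergence threshold (default `1e-5`).
#' @param max_iterations Iteration cap (default 500).
#' @param init_method One of `"partition"`, `"d2_random"`,
#'   `"methylation"`.
#' @param seed Optional integer seed used by the randomized (`d2_random`)
#'   initialization.
#' @param variance_floor,mean_clamp Degeneracy guards, see Details.
#' @return A list of class `betamix_config`.
#' @export
fit_config <- function(tol = 1e-5, max_iterations = 500L,
                       init_method = c("partition", "d2_random", "methylation"),
                       seed = NULL, variance_floor = 1e-10,
                       mean_clamp = 1e-6) {
  stopifnot(tol > 0, max_iterations >= 1)
  structure(list(tol = tol, max_iterations = as.integer(max_iterations),
                 init_method = match.arg(init_method), seed = seed,
                 variance_floor = variance_floor, mean_clamp = mean_clamp),
            class = "betamix_config")
}

# Clamp a (mean, variance) pair into the region where the moment map is
# defined.  Shared by every moment-based estimation path (initializers and
# the MM-step) so they agree on degenerate windows.
regularize_moments <- function(mean, variance, cfg = fit_config()) {
  mean <- min(max(mean, cfg$mean_clamp), 1 - cfg$mean_clamp)
  variance <- max(variance, cfg$variance_floor)
  variance <- min(variance, (1 - 1e-6) * mean * (1 - mean))
  list(mean = mean, variance = variance)
}

# Population-variance sample moments (divide by count), the convention
# used throughout: it matches the responsibility-weighted MM-step moments.
sample_moments <- function(x) {
  m <- mean(x)
  list(mean = m, variance = mean((x - m)^2))
}

moments_to_shapes <- function(mean, variance, cfg = fit_config()) {
  m <- regularize_moments(mean, variance, cfg)
  p <- moments_to_params(m$mean, m$variance)
  c(alpha = p$alpha, beta = p$beta)
}

#' Responsibility (E-) step
#'
#' Computes the posterior probability W\[i, j\] that observation i arose
#' from component j.  Interior points use Bayes' rule on the component
#' densities (normalized in log space, so joint underflow cannot occur).
#' Observations exactly at 0 or 1 -- where beta densities are singular --
#' are instead assigned entirely to the boundary components returned by
#' [boundary_components()]: their rows are exact indicator vectors.
#' Column means of W give the updated mixture coefficients.
#'
#' @param x Numeric vector in `[0, 1]`.
#' @param model A [beta_mixture()] object.
#' @return A list with `W` (n x c responsibility matrix, rows summing
#'   to 1) and `pi_plus` (updated mixture coefficients, `colMeans(W)`).
#' @export
e_step <- function(x, model) {
  stopifnot(inherits(model, "beta_mixture"))
  check_unit_interval(x)
  n <- length(x)
  k <- model$c
  W <- matrix(0, n, k)
  interior <- x > 0 & x < 1
  if (any(interior)) {
    xi <- x[interior]
    lw <- matrix(-Inf, length(xi), k)
    for (j in seq_len(k)) {
      if (model$weights[j] > 0) {
        lw[, j] <- log(model$weights[j]) +
          stats::dbeta(xi, model$alpha[j], model$beta[j], log = TRUE)
      }
    }
    mx <- apply(lw, 1L, max)
    Wi <- exp(lw - mx)
    W[interior, ] <- Wi / rowSums(Wi)
  }
  bc <- boundary_components(model)
  W[x == 0, bc[["j0"]]] <- 1
  W[x == 1, bc[["j1"]]] <- 1
  list(W = W, pi_plus = colMeans(W))
}

#' Method of moments (MM-) step
#'
#' Re-estimates each component from its responsibility-weighted sample
#' moments: mu_j = sum_i W\[i,j\] x_i / (n pi_j) and
#' sigma2_j = sum_i W\[i,j\] (x_i - mu_j)^2 / (n pi_j), then maps
#' (mu_j, sigma2_j) to shape parameters via the inverse moment equations
#' (after the degeneracy guards in [fit_config()]).  The updated mixture
#' coefficients are `pi_plus`.  Components with vanishing weight
#' (pi below 1e-12) are dropped and the remaining weights renormalized.
#'
#' @param x Numeric vector in `[0, 1]`.
#' @param W Responsibility matrix from [e_step()].
#' @param pi_plus Updated mixture coefficients (`colMeans(W)`).
#' @param cfg A [fit_config()].
#' @return A [beta_mixture()] (unsorted: component identity preserved),
#'   with attribute `dropped` giving the indices of removed components
#'   (if any).
#' @export
mm_step <- function(x, W, pi_plus, cfg = fit_config()) {
  n <- length(x)
  keep <- pi_plus > 1e-12
  dropped <- which(!keep)
  if (!any(keep)) stop("all components lost their weight", call. = FALSE)
  W <- W[, keep, drop = FALSE]
  pi_plus <- pi_plus[keep]
  if (length(dropped)) {
    W <- W / rowSums(W)
    pi_plus <- colMeans(W)
  }
  k <- length(pi_plus)
  alpha <- beta <- raw_means <- numeric(k)
  for (j in seq_len(k)) {
    denom <- n * pi_plus[j]
    mu <- sum(W[, j] * x) / denom
    s2 <- sum(W[, j] * (x - mu)^2) / denom
    raw_means[j] <- mu
    sh <- moments_to_shapes(mu, s2, cfg)
    alpha[j] <- sh[["alpha"]]
    beta[j] <- sh[["beta"]]
  }
  out <- beta_mixture(pi_plus / sum(pi_plus), alpha, beta, sort = FALSE)
  attr(out, "dropped") <- dropped
  # weighted means before the degeneracy guards; the mixture expectation
  # sum_j pi_j * raw_mean_j equals the sample mean exactly
  attr(out, "raw_means") <- raw_means
  out
}

#' Relative parameter change
#'
#' kappa = |new - old| / max(|new|, |old|), with kappa = 0 when both
#' values are 0.  Used by the stationarity-based termination rule.
#'
#' @param old,new Numeric vectors (recycled).
#' @return Nonnegative numeric vector of relative changes.
#' @export
relative_change <- function(old, new) {
  denom <- pmax(abs(old), abs(new))
  ifelse(denom == 0, 0, abs(new - old) / denom)
}

#' Initialization strategies
#'
#' `init_partition()` spreads `c` components over the unit interval: the
#' k-th (k = 0, ..., c-1) is centered at k/(c-1) and its moments are
#' estimated from the data in `[(k-1)/(c-1), (k+1)/(c-1)]` intersected
#' with `[0, 1]`; components whose window is empty are removed, and the
#' initial weights are proportional to the window point counts.  For
#' c = 2 both windows are all of `[0, 1]` and the two components would be
#' identical forever; their means are nudged apart by
#' `min(0.01, (max(x) - min(x)) / 10)` to break the symmetry.
#'
#' `init_d2_weighted()` adapts the D^2-weighted seeding of k-means++:
#' centers are drawn greedily from the distinct data values, each new one
#' with probability proportional to its squared distance to the nearest
#' chosen center; component j's moments come from the data within
#' `[y_j - 0.5, y_j + 0.5]` and weights from those window counts.
#'
#' `init_methylation()` is the three-state variant used for methylation
#' levels: component moments from the data in `[0, 0.25]`, `(0.25, 0.75]`
#' and `(0.75, 1]`.  The unmethylated component is forced to a falling
#' density (alpha1 = 0.8 if its moment estimate exceeds 0.8) and the
#' fully methylated one to a rising density (beta3 = 0.8 likewise).  An
#' empty interval falls back to a diffuse default component for that
#' state -- Beta(0.8, 5), Beta(5, 5) or Beta(5, 0.8) -- with a floor
#' weight of 1/n.
#'
#' @param x Numeric data vector in `[0, 1]`.
#' @param c Number of components requested.
#' @param seed Optional seed for the randomized draw.
#' @param cfg A [fit_config()] (for the moment-degeneracy guards).
#' @return A [beta_mixture()] start model (possibly with fewer than `c`
#'   components for `init_partition`).
#' @export
init_partition <- function(x, c, cfg = fit_config()) {
  check_unit_interval(x)
  stopifnot(c >= 1, length(x) >= 1)
  if (c == 1L) {
    m <- sample_moments(x)
    sh <- moments_to_shapes(m$mean, m$variance, cfg)
    return(beta_mixture(1, sh[["alpha"]], sh[["beta"]], sort = FALSE))
  }
  centers <- (seq_len(c) - 1) / (c - 1)
  lo <- pmax(centers - 1 / (c - 1), 0)
  hi <- pmin(centers + 1 / (c - 1), 1)
  alpha <- beta <- counts <- numeric(0)
  for (k in seq_len(c)) {
    sel <- x >= lo[k] & x <= hi[k]
    if (!any(sel)) next  # empty window: component removed
    m <- sample_moments(x[sel])
    mu <- m$mean
    if (c == 2L) {  # symmetric windows; break the tie
      nudge <- min(0.01, (max(x) - min(x)) / 10)
      mu <- mu + if (k == 1L) -nudge else nudge
    }
    sh <- moments_to_shapes(mu, m$variance, cfg)
    alpha <- c(alpha, sh[["alpha"]])
    beta <- c(beta, sh[["beta"]])
    counts <- c(counts, sum(sel))
  }
  beta_mixture(counts / sum(counts), alpha, beta, sort = FALSE)
}

#' @rdname init_partition
#' @export
init_d2_weighted <- function(x, c, seed = NULL, cfg = fit_config()) {
  check_unit_interval(x)
  vals <- sort(unique(x))
  if (length(vals) < c) {
    stop("fewer distinct data values than components", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  y <- vals[sample.int(length(vals), 1L)]
  while (length(y) < c) {
    rest <- setdiff(vals, y)
    d2 <- vapply(rest, function(v) min(abs(v - y))^2, numeric(1))
    y <- c(y, if (all(d2 == 0)) rest[1L] else
      rest[sample.int(length(rest), 1L, prob = d2)])
  }
  y <- sort(y)
  alpha <- beta <- counts <- numeric(c)
  for (j in seq_len(c)) {
    sel <- x >= y[j] - 0.5 & x <= y[j] + 0.5
    m <- sample_moments(x[sel])
    sh <- moments_to_shapes(m$mean, m$variance, cfg)
    alpha[j] <- sh[["alpha"]]
    beta[j] <- sh[["beta"]]
    counts[j] <- sum(sel)
  }
  beta_mixture(counts / sum(counts), alpha, beta, sort = FALSE)
}

#' @rdname init_partition
#' @export
init_methylation <- function(x, cfg = fit_config()) {
  check_unit_interval(x)
  stopifnot(length(x) >= 1)
  n <- length(x)
  sel <- list(x <= 0.25, x > 0.25 & x <= 0.75, x > 0.75)
  defaults <- list(c(0.8, 5), c(5, 5), c(5, 0.8))
  alpha <- beta <- counts <- numeric(3)
  for (j in 1:3) {
    if (any(sel[[j]])) {
      m <- sample_moments(x[sel[[j]]])
      sh <- moments_to_shapes(m$mean, m$variance, cfg)
      alpha[j] <- sh[["alpha"]]
      beta[j] <- sh[["beta"]]
      counts[j] <- sum(sel[[j]])
    } else {
      alpha[j] <- defaults[[j]][1]
      beta[j] <- defaults[[j]][2]
      counts[j] <- 1  # floor weight 1/n before renormalization
    }
  }
  # enforce falling density near 0 and rising density near 1
  if (alpha[1] > 0.8) alpha[1] <- 0.8
  if (beta[3] > 0.8) beta[3] <- 0.8
  beta_mixture(counts / sum(counts), alpha, beta, sort = FALSE)
}

build_init <- function(x, c, cfg) {
  switch(cfg$init_method,
         partition = init_partition(x, c, cfg),
         d2_random = init_d2_weighted(x, c, seed = cfg$seed, cfg = cfg),
         methylation = {
           if (c != 3L) stop("methylation initialization requires c = 3",
                             call. = FALSE)
           init_methylation(x, cfg)
         })
}

#' Fit a beta mixture by the iterated method of moments
#'
#' Alternates the responsibility step ([e_step()]) with method of moments
#' re-estimation of every component ([mm_step()]) until all parameters
#' are stationary: the relative change of every alpha_j, beta_j and pi_j
#' falls below `cfg$tol`, or `cfg$max_iterations` is reached.  Because
#' the E-step assigns observations exactly at 0 or 1 to dedicated
#' boundary components and no likelihood is ever evaluated there, the fit
#' never fails on data containing 0s and 1s.
#'
#' After termination one extra responsibility step is run so the returned
#' weights correspond to the returned (final) parameters.
#'
#' @param x Numeric data in `[0, 1]`.
#' @param c Number of components to start from (the fit may drop
#'   components whose weight vanishes).
#' @param cfg A [fit_config()].
#' @param init Optional explicit [beta_mixture()] start model, overriding
#'   `cfg$init_method`.
#' @param engine `"cpp"` (default, compiled loop) or `"r"` (reference
#'   loop composed from [e_step()] and [mm_step()]; identical arithmetic).
#' @return An object of class `betamix_fit`: `model` (canonically sorted
#'   by ascending mean), `responsibilities` (columns in the same order),
#'   `iterations`, `converged`, `final_max_relative_change`,
#'   `mixture_mean_trace` (per-iteration expectation of the fitted
#'   density, used to verify that it always equals the sample mean) and
#'   `n_dropped`.
#' @examples
#' x <- c(rep(0, 10), seq(0.01, 0.10, by = 0.01))
#' betamix_fit(x, c = 1)$model
#' @export
betamix_fit <- function(x, c, cfg = fit_config(), init = NULL,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_unit_interval(x)
  stopifnot(length(x) >= 1, c >= 1)
  model0 <- if (is.null(init)) build_init(x, as.integer(c), cfg) else init
  raw <- if (engine == "cpp") {
    fit_engine_cpp(x, model0$weights, model0$alpha, model0$beta,
                   cfg$tol, cfg$max_iterations, cfg$mean_clamp,
                   cfg$variance_floor)
  } else {
    fit_engine_r(x, model0, cfg)
  }
  model <- beta_mixture(raw$weights, raw$alpha, raw$beta, sort = FALSE)
  ord <- order(component_means(model))
  model <- beta_mixture(model$weights[ord], model$alpha[ord],
                        model$beta[ord], sort = FALSE)
  structure(
    list(model = model,
         responsibilities = raw$W[, ord, drop = FALSE],
         iterations = raw$iterations,
         converged = raw$converged,
         final_max_relative_change = raw$final_max_relative_change,
         mixture_mean_trace = raw$mean_trace,
         n_dropped = raw$n_dropped),
    class = "betamix_fit"
  )
}

#' @export
print.betamix_fit <- function(x, ...) {
  cat(sprintf("Iterated method of moments fit (%d iteration(s), %s)\n",
              x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$model)
  invisible(x)
}

# Reference loop in pure R; same arithmetic as the compiled engine.
fit_engine_r <- function(x, model, cfg) {
  n_dropped <- 0L
  mean_trace <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  max_rel <- Inf
  W <- NULL
  for (it in seq_len(cfg$max_iterations)) {
    iterations <- it
    es <- e_step(x, model)
    new_model <- mm_step(x, es$W, es$pi_plus, cfg)
    dropped <- attr(new_model, "dropped")
    mean_trace <- c(mean_trace,
                    sum(new_model$weights * attr(new_model, "raw_means")))
    if (length(dropped)) {
      n_dropped <- n_dropped + length(dropped)
      model <- new_model
      max_rel <- Inf  # parameter sets not comparable this iteration
      next
    }
    max_rel <- max(relative_change(
      c(model$weights, model$alpha, model$beta),
      c(new_model$weights, new_model$alpha, new_model$beta)))
    model <- new_model
    if (max_rel < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  W <- e_step(x, model)$W
  list(weights = model$weights, alpha = model$alpha, beta = model$beta,
       W = W, iterations = iterations, converged = converged,
       final_max_relative_change = max_rel, mean_trace = mean_trace,
       n_dropped = n_dropped)
}
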