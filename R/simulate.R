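#' Random mixture coefficients
#'
#' Draws c uniform variates and normalizes them to sum to 1.  Unlike
#' uniform sampling from the probability simplex (Dirichlet(1, ..., 1)),
#' this biases towards mixtures whose components have similar
#' coefficients, which is the intended regime for methylation data where
#' all three states should be represented.
#'
#' @param c Number of components.
#' @return A simplex vector of length `c`.
#' @export
draw_mixture_weights <- function(c) {
  stopifnot(c >= 1)
  repeat {
    u <- stats::runif(c)
    if (sum(u) > 0) return(u / sum(u))
  }
}

#' Random three-state methylation mixture
#'
#' Generates a three-component truth model for the class-assignment
#' benchmark.  With U denoting independent uniforms on `[0, 1]`:
#' the unmethylated component has alpha = U1 (<= 1, density falling or
#' flat) and beta = 1/U2 (>= 1); the fully methylated component is its
#' mirror image (alpha = 1/U, beta = U); the semi-methylated component
#' has gamma = 5 / min(U1, U2), V uniform on `[0.9, 1.1]`,
#' alpha = gamma V and beta = gamma / V, giving a concentrated,
#' near-symmetric peak with mean in about `[0.45, 0.55]`.  Mixture
#' coefficients come from [draw_mixture_weights()].
#'
#' @return A [beta_mixture()] in state order (unmethylated,
#'   semi-methylated, fully methylated); labels from [sample_mixture()]
#'   refer to this order.
#' @export
gen_methylation_mixture <- function() {
  w <- draw_mixture_weights(3)
  u <- stats::runif(2)
  a1 <- u[1]; b1 <- 1 / u[2]
  u <- stats::runif(2)
  b3 <- u[1]; a3 <- 1 / u[2]
  u <- stats::runif(2)
  gam <- 5 / min(u)
  v <- stats::runif(1, 0.9, 1.1)
  beta_mixture(w, alpha = c(a1, gam * v, a3), beta = c(b1, gam / v, b3),
               sort = FALSE)
}

#' Random mixtures for the component-number benchmark
#'
#' `gen_independent_mixture()` draws each component independently:
#' alpha is standard exponential and beta = 1 - E with E standard
#' exponential, the pair redrawn until beta > 0 (so beta is in (0, 1)).
#' Independent components frequently overlap, producing data describable
#' by fewer components than generated.
#'
#' `gen_realistic_mixture()` produces separable components spread over a
#' random sub-interval I = `[E1, 1 - E2]` with exponentially distributed
#' borders (redrawn while the interval is inverted or too small to hold
#' c means at pairwise distance 0.2, with a 0.02 margin).  Component
#' means are uniform in I, redrawn as a set while any two are closer
#' than 0.2 (up to 10^4 attempts, then a fresh interval).  Each
#' component's standard deviation is d/4, where d is the distance to the
#' nearest other mean or interval border, so adjacent components only
#' slightly overlap; (mean, sd^2) are mapped to shape parameters through
#' the inverse moment equations.
#'
#' @param c Number of components.
#' @return A [beta_mixture()]; realistic mixtures are in ascending-mean
#'   order by construction.
#' @export
gen_independent_mixture <- function(c) {
  stopifnot(c >= 1)
  alpha <- beta <- numeric(c)
  for (j in seq_len(c)) {
    repeat {
      a <- stats::rexp(1)
      b <- 1 - stats::rexp(1)
      if (b > 0) break
    }
    alpha[j] <- a
    beta[j] <- b
  }
  beta_mixture(draw_mixture_weights(c), alpha, beta, sort = FALSE)
}

#' @rdname gen_independent_mixture
#' @export
gen_realistic_mixture <- function(c) {
  stopifnot(c >= 1)
  repeat {
    lo <- stats::rexp(1)
    hi <- 1 - stats::rexp(1)
    if (hi < lo || hi - lo < 0.2 * (c - 1) + 0.02) next
    mu <- NULL
    for (attempt in seq_len(10000L)) {
      m <- sort(stats::runif(c, lo, hi))
      if (c == 1L || min(diff(m)) >= 0.2) {
        mu <- m
        break
      }
    }
    if (is.null(mu)) next
    d <- pmin(mu - lo, hi - mu)
    if (c > 1L) {
      nn <- pmin(c(diff(mu), Inf), c(Inf, diff(mu)))
      d <- pmin(d, nn)
    }
    sigma2 <- (d / 4)^2
    if (any(sigma2 >= mu * (1 - mu))) next  # cannot occur for d <= 1; guard anyway
    alpha <- beta <- numeric(c)
    for (j in seq_len(c)) {
      p <- moments_to_params(mu[j], sigma2[j])
      alpha[j] <- p$alpha
      beta[j] <- p$beta
    }
    return(beta_mixture(draw_mixture_weights(c), alpha, beta, sort = FALSE))
  }
}

#' Sample labeled data from a mixture
#'
#' Draws the generating component per observation according to the
#' mixture coefficients, then the value from that component's beta
#' distribution.
#'
#' @param model A [beta_mixture()] truth model.
#' @param n Sample size.
#' @return A list of class `labeled_sample` with `values`, `labels`
#'   (generating component indices) and `truth` (the model).
#' @export
sample_mixture <- function(model, n) {
  stopifnot(inherits(model, "beta_mixture"), n >= 1)
  labels <- sample.int(model$c, n, replace = TRUE, prob = model$weights)
  values <- stats::rbeta(n, model$alpha[labels], model$beta[labels])
  structure(list(values = values, labels = labels, truth = model),
            class = "labeled_sample")
}

#' Clamp the extreme sample values to the boundaries
#'
#' Replaces the k smallest values by 0.0 and the k largest by 1.0,
#' emulating levels observed exactly at the boundaries; the generating
#' labels are unchanged.  The benchmark configurations use k = 3 for
#' n = 200 and k = 10 for n = 1000.
#'
#' @param sample A `labeled_sample` (or plain numeric vector).
#' @param k Number of values to clamp at each end; `2k <= n`.
#' @return The sample with clamped values.
#' @export
clamp_extremes <- function(sample, k) {
  vals <- if (inherits(sample, "labeled_sample")) sample$values else sample
  n <- length(vals)
  stopifnot(k >= 0, 2 * k <= n)
  if (k > 0) {
    ord <- order(vals)
    vals[ord[seq_len(k)]] <- 0.0
    vals[ord[seq.int(n - k + 1, n)]] <- 1.0
  }
  if (inherits(sample, "labeled_sample")) {
    sample$values <- vals
    sample
  } else {
    vals
  }
}

# Deterministic per-unit child seeds derived from one master seed, so
# studies are reproducible end to end and units are independent streams.
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Map fitted components to methylation states 1..3.  A three-component
# fit in ascending-mean order is the identity; if the fit dropped
# components, each survivor is matched to the nearest state anchor
# (0, 0.5, 1) by its mean.
state_map <- function(model) {
  if (model$c == 3L) return(1:3)
  anchors <- c(0, 0.5, 1)
  vapply(component_means(model),
         function(m) which.min(abs(m - anchors)), integer(1))
}

#' Class-assignment benchmark
#'
#' The full simulation study comparing adaptive, mixture-based state
#' assignment against fixed thresholds.  Per mixture: generate a random
#' three-state truth model ([gen_methylation_mixture()]), draw
#' `n_samples` labeled values, clamp the `k_clamp` smallest/largest to
#' 0/1, fit a three-component mixture with the methylation
#' initialization, sweep the fixed-interval rule and both weight-based
#' rules, and compute the signed area between the max-weight rule's and
#' the fixed rule's correct-fraction-vs-assigned-fraction curves.
#' Positive area means mixture modeling classified better on that
#' mixture.  Areas with absolute value at most `1e-6` count as ties.
#'
#' @param n_mixtures Number of simulated mixtures (1000 in the reference
#'   configurations).
#' @param n_samples Values per mixture (200 or 1000).
#' @param k_clamp Values clamped to each boundary (3 or 10).
#' @param seed Master seed; every mixture gets a derived child seed.
#' @param cfg A [fit_config()]; the initialization is always the
#'   methylation one.
#' @return A list of class `class_assignment_study`: `results` (one row
#'   per mixture: signed areas for both weight rules, sign class, fit
#'   diagnostics), `n_pos`, `n_neg`, `n_zero`, `mean_area`, and the
#'   configuration.
#' @export
run_class_assignment_study <- function(n_mixtures, n_samples, k_clamp,
                                       seed = 1L, cfg = fit_config()) {
  seeds <- child_seeds(seed, n_mixtures)
  area <- area_gap <- rep(NA_real_, n_mixtures)
  iterations <- c_fit <- integer(n_mixtures)
  converged <- logical(n_mixtures)
  failures <- 0L
  for (i in seq_len(n_mixtures)) {
    set.seed(seeds[i])
    res <- tryCatch({
      truth <- gen_methylation_mixture()
      smp <- clamp_extremes(sample_mixture(truth, n_samples), k_clamp)
      fit <- betamix_fit(smp$values, 3L, cfg,
                         init = init_methylation(smp$values, cfg))
      map <- state_map(fit$model)
      W <- fit$responsibilities
      truth_lab <- smp$labels
      curve_fixed <- performance_curve(smp$values, truth = truth_lab,
                                       rule = "fixed")
      # weight-based rules label fitted components; translate to states
      curve_w <- weight_curve(W, map, truth_lab, gap = FALSE)
      curve_g <- weight_curve(W, map, truth_lab, gap = TRUE)
      list(a = suppressWarnings(signed_area_between(curve_w, curve_fixed)),
           g = suppressWarnings(signed_area_between(curve_g, curve_fixed)),
           it = fit$iterations, cv = fit$converged, k = fit$model$c)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    area[i] <- res$a
    area_gap[i] <- res$g
    iterations[i] <- res$it
    converged[i] <- res$cv
    c_fit[i] <- res$k
  }
  ok <- !is.na(area)
  sign_class <- ifelse(abs(area[ok]) <= 1e-6, "0",
                       ifelse(area[ok] > 0, "+", "-"))
  structure(list(
    results = data.frame(mixture = seq_len(n_mixtures), area = area,
                         area_gap = area_gap, iterations = iterations,
                         converged = converged, c_fit = c_fit),
    n_pos = sum(sign_class == "+"),
    n_neg = sum(sign_class == "-"),
    n_zero = sum(sign_class == "0"),
    mean_area = mean(area[ok]),
    failures = failures,
    config = list(n_mixtures = n_mixtures, n_samples = n_samples,
                  k_clamp = k_clamp, seed = seed)),
    class = "class_assignment_study")
}

weight_curve <- function(W, map, truth_lab, gap) {
  n <- nrow(W)
  sweep <- seq(0, 1, length.out = 101)
  rule <- if (gap) rule_weight_gap else rule_max_weight
  N <- C <- numeric(length(sweep))
  for (i in seq_along(sweep)) {
    lab <- rule(W, sweep[i])
    st <- ifelse(is.na(lab), NA_integer_, map[lab])
    nc <- evaluate_rule(st, truth_lab)
    N[i] <- nc[["N"]]
    C[i] <- nc[["C"]]
  }
  out <- data.frame(threshold = sweep, assigned_fraction = N / n,
                    correct_fraction = C / n,
                    precision = ifelse(N > 0, C / N, NA_real_))
  class(out) <- c("performance_curve", "data.frame")
  out
}

#' @export
print.class_assignment_study <- function(x, ...) {
  cat(sprintf(
    "Class-assignment study (%d mixtures, n = %d, clamp %d):\n",
    x$config$n_mixtures, x$config$n_samples, x$config$k_clamp))
  cat(sprintf("  signed area (+/-/0): %d / %d / %d   mean area: %+.4g\n",
              x$n_pos, x$n_neg, x$n_zero, x$mean_area))
  invisible(x)
}

#' Component-number benchmark
#'
#' For each true component count in `c_range`, generates `n_datasets`
#' mixtures of the given `kind`, samples `n_samples` values from each,
#' and estimates the number of components with the sequential KS
#' stopping rule ([select_components()]).  Per-dataset KS p-values for
#' every tried component count are cached (fits continue until the
#' p-value reaches `cache_threshold`) so [sweep_p_threshold()] can
#' re-run the selection at other thresholds without refitting.
#'
#' @param kind `"independent"` or `"realistic"` generator.
#' @param c_range True component counts (default 1:5).
#' @param n_datasets Datasets per true count.
#' @param n_samples Values per dataset (1000 in the reference
#'   configuration).
#' @param p_threshold KS p-value stopping threshold (default 0.5).
#' @param c_max Largest candidate count (default `max(c_range) + 1`).
#' @param seed Master seed.
#' @param cfg A [fit_config()].
#' @param cache_threshold Cache fits up to this p-value (default 0.99).
#' @return A list of class `component_number_study`: `results` (dataset,
#'   c_true, c_hat, reached), `confusion` (true x estimated counts; each
#'   column of the transposed display sums to `n_datasets`), `p_values`
#'   (per-dataset cached vectors) and the configuration.
#' @export
run_component_number_study <- function(kind = c("independent", "realistic"),
                                       c_range = 1:5, n_datasets,
                                       n_samples = 1000L, p_threshold = 0.5,
                                       c_max = max(c_range) + 1L,
                                       seed = 1L, cfg = fit_config(),
                                       cache_threshold = 0.99) {
  kind <- match.arg(kind)
  gen <- switch(kind, independent = gen_independent_mixture,
                realistic = gen_realistic_mixture)
  total <- length(c_range) * n_datasets
  seeds <- child_seeds(seed, total)
  c_true <- rep(c_range, each = n_datasets)
  c_hat <- integer(total)
  reached <- logical(total)
  p_values <- vector("list", total)
  for (i in seq_len(total)) {
    set.seed(seeds[i])
    truth <- gen(c_true[i])
    smp <- sample_mixture(truth, n_samples)
    sel <- select_components(smp$values, c_max, p_threshold, cfg,
                             cache_threshold = cache_threshold)
    c_hat[i] <- sel$c_hat
    reached[i] <- sel$reached
    p_values[[i]] <- sel$p_value
  }
  confusion <- table(true = factor(c_true, levels = c_range),
                     estimated = factor(c_hat, levels = seq_len(c_max)))
  structure(list(
    results = data.frame(dataset = seq_len(total), c_true = c_true,
                         c_hat = c_hat, reached = reached),
    confusion = confusion, p_values = p_values,
    config = list(kind = kind, c_range = c_range, n_datasets = n_datasets,
                  n_samples = n_samples, p_threshold = p_threshold,
                  c_max = c_max, seed = seed,
                  cache_threshold = cache_threshold)),
    class = "component_number_study")
}

#' @export
print.component_number_study <- function(x, ...) {
  cat(sprintf("Component-number study (%s generator, %d datasets per c):\n",
              x$config$kind, x$config$n_datasets))
  print(x$confusion)
  invisible(x)
}

#' Re-run component selection across p-value thresholds
#'
#' Uses the p-values cached by [run_component_number_study()] to apply
#' the stopping rule at each threshold in `thresholds` and reports the
#' under- and overestimation rates and their sum.  Thresholds above the
#' study's cache threshold would require fits that were not performed
#' and are rejected.
#'
#' @param study A `component_number_study`.
#' @param thresholds Numeric grid in (0, 1).
#' @return A data.frame with columns `threshold`, `under`, `over`,
#'   `total`.
#' @export
sweep_p_threshold <- function(study,
                              thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(study, "component_number_study"),
            all(thresholds > 0), all(thresholds < 1))
  if (any(thresholds > study$config$cache_threshold)) {
    stop("thresholds above the study's cache_threshold require refitting",
         call. = FALSE)
  }
  c_true <- study$results$c_true
  c_max <- study$config$c_max
  out <- lapply(thresholds, function(th) {
    c_hat <- vapply(study$p_values, reselect_components, integer(1),
                    p_threshold = th, c_max = c_max)
    data.frame(threshold = th,
               under = mean(c_hat < c_true),
               over = mean(c_hat > c_true),
               total = mean(c_hat != c_true))
  })
  do.call(rbind, out)
}
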