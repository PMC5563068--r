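#' Kolmogorov-Smirnov distance between a fitted mixture and the data
#'
#' The supremum distance between the mixture cdf and the empirical cdf.
#' With sorted data x_(1) <= ... <= x_(n) the supremum is attained at a
#' data point, approached from one side or the other, so both sides of
#' each empirical step are evaluated:
#' `max_i max(|F(x_(i)) - i/n|, |F(x_(i)) - (i-1)/n|)`.
#'
#' @param x Numeric data in `[0, 1]`.
#' @param model A [beta_mixture()] object.
#' @return The KS distance, a number in `[0, 1]`.
#' @export
ks_distance <- function(x, model) {
  stopifnot(length(x) >= 1)
  n <- length(x)
  Fx <- mixture_cdf(sort(x), model)
  i <- seq_len(n)
  max(abs(Fx - i / n), abs(Fx - (i - 1) / n))
}

#' Asymptotic p-value of the Kolmogorov-Smirnov statistic
#'
#' Converts a KS distance into the p-value of the one-sample KS test via
#' the asymptotic Kolmogorov distribution with the standard small-sample
#' correction: lambda = (sqrt(n) + 0.12 + 0.11/sqrt(n)) * distance and
#' p = Q(lambda) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2),
#' clipped to `[0, 1]`.
#'
#' @param distance KS distance in `[0, 1]`.
#' @param n Sample size.
#' @return A p-value in `[0, 1]`, decreasing in `distance` and (at fixed
#'   distance) in `n`.
#' @export
ks_pvalue <- function(distance, n) {
  stopifnot(n >= 1, distance >= 0)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * distance
  if (lambda == 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' KS goodness of fit of a mixture model
#'
#' @param x Numeric data in `[0, 1]`.
#' @param model A [beta_mixture()] object.
#' @return A list of class `ks_result` with `distance`, `p_value`, `n`.
#' @export
ks_test_mixture <- function(x, model) {
  d <- ks_distance(x, model)
  structure(list(distance = d, p_value = ks_pvalue(d, length(x)),
                 n = length(x)), class = "ks_result")
}

#' Select the number of mixture components
#'
#' Fits mixtures with c = 1, 2, ... components sequentially and stops at
#' the first c whose fitted model's KS p-value reaches `p_threshold`
#' (the distance drops with every added component; no likelihood-based
#' criterion such as AIC/BIC applies because the fit is not
#' likelihood-based).  If no c up to `c_max` reaches the threshold,
#' `c_max` is returned and flagged.
#'
#' @param x Numeric data in `[0, 1]`.
#' @param c_max Largest component count to try.
#' @param p_threshold Stopping p-value in (0, 1); default 0.5, which
#'   demands a clearly non-significant deviation between fit and data.
#' @param cfg A [fit_config()].
#' @param cache_threshold Continue fitting past the stopping point until
#'   the p-value reaches this level (or `c_max`), caching every fit; used
#'   by the threshold-sweep analysis so selection can be re-run at any
#'   threshold up to `cache_threshold` without refitting.  Default equal
#'   to `p_threshold` (no extra fits).
#' @return A list of class `betamix_selection`: `c_hat`, `reached`
#'   (did some c meet the threshold?), `fits` (per-c [betamix_fit()]
#'   list), `distance` and `p_value` vectors indexed by c.
#' @export
select_components <- function(x, c_max, p_threshold = 0.5,
                              cfg = fit_config(),
                              cache_threshold = p_threshold) {
  stopifnot(c_max >= 1, p_threshold > 0, p_threshold < 1)
  cache_threshold <- max(cache_threshold, p_threshold)
  fits <- vector("list", c_max)
  distance <- p_value <- rep(NA_real_, c_max)
  for (cc in seq_len(c_max)) {
    fits[[cc]] <- betamix_fit(x, cc, cfg)
    ks <- ks_test_mixture(x, fits[[cc]]$model)
    distance[cc] <- ks$distance
    p_value[cc] <- ks$p_value
    if (ks$p_value >= cache_threshold) break
  }
  tried <- which(!is.na(p_value))
  hit <- tried[p_value[tried] >= p_threshold]
  c_hat <- if (length(hit)) hit[1L] else c_max
  structure(list(c_hat = c_hat, reached = length(hit) > 0,
                 fits = fits, distance = distance, p_value = p_value),
            class = "betamix_selection")
}

# Re-run the stopping rule on cached p-values at a different threshold.
reselect_components <- function(p_value, p_threshold, c_max) {
  tried <- which(!is.na(p_value))
  hit <- tried[p_value[tried] >= p_threshold]
  if (length(hit)) hit[1L] else as.integer(c_max)
}
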