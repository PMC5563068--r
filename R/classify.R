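#' Methylation-state assignment rules
#'
#' Three rules assign each observed level to a state (1 = unmethylated,
#' 2 = semi-methylated, 3 = fully methylated for the usual c = 3 setting)
#' or leave it unassigned (`NA`):
#'
#' * `rule_fixed()`: fixed intervals with slack `s` in `[0, 0.25]` --
#'   state 1 for x in `[0, 0.25 - s]`, state 2 for x in
#'   `(0.25 + s, 0.75 - s]`, state 3 for x in `(0.75 + s, 1]`; anything
#'   else (the slack bands) is unassigned.  The rule ignores the fitted
#'   model entirely.
#' * `rule_max_weight()`: the component with the largest responsibility
#'   weight, unassigned when that weight is below `t`.
#' * `rule_weight_gap()`: the same argmax, unassigned when the gap to the
#'   second-largest weight is below `t` (for a single-component model the
#'   gap is the weight itself).
#'
#' Ties in the argmax are broken by the lowest component index.
#'
#' @param x Numeric vector of levels in `[0, 1]`.
#' @param s Slack in `[0, 0.25]`.
#' @param W Responsibility matrix (rows sum to 1), e.g. from
#'   [betamix_fit()].
#' @param t Threshold in `[0, 1]`.
#' @return Integer vector of state labels with `NA` for unassigned
#'   points.
#' @export
rule_fixed <- function(x, s) {
  check_unit_interval(x)
  stopifnot(s >= 0, s <= 0.25)
  lab <- rep(NA_integer_, length(x))
  lab[x >= 0 & x <= 0.25 - s] <- 1L
  lab[x > 0.25 + s & x <= 0.75 - s] <- 2L
  lab[x > 0.75 + s & x <= 1] <- 3L
  lab
}

#' @rdname rule_fixed
#' @export
rule_max_weight <- function(W, t) {
  stopifnot(t >= 0, t <= 1)
  j_star <- max.col(W, ties.method = "first")
  w_star <- W[cbind(seq_len(nrow(W)), j_star)]
  ifelse(w_star < t, NA_integer_, j_star)
}

#' @rdname rule_fixed
#' @export
rule_weight_gap <- function(W, t) {
  stopifnot(t >= 0, t <= 1)
  j_star <- max.col(W, ties.method = "first")
  n <- nrow(W)
  w_star <- W[cbind(seq_len(n), j_star)]
  if (ncol(W) == 1L) {
    gap <- w_star
  } else {
    W2 <- W
    W2[cbind(seq_len(n), j_star)] <- -Inf
    gap <- w_star - apply(W2, 1L, max)
  }
  ifelse(gap < t, NA_integer_, j_star)
}

#' Count assigned and correctly assigned points
#'
#' @param assignments Integer labels with `NA` for unassigned points.
#' @param truth Integer vector of true generating components.
#' @return Named integer vector `c(N = assigned, C = correct)`; always
#'   `C <= N`.
#' @export
evaluate_rule <- function(assignments, truth) {
  stopifnot(length(assignments) == length(truth))
  assigned <- !is.na(assignments)
  c(N = sum(assigned),
    C = sum(assigned & assignments == truth, na.rm = TRUE))
}

#' Performance curve of an assignment rule over a threshold sweep
#'
#' Sweeps the rule's threshold and records, per threshold value, the
#' assigned fraction N/n, the correct fraction C/n and the precision C/N
#' (NA when nothing is assigned).  Assignment sets are nested along the
#' sweep, so the assigned fraction is monotone nonincreasing.
#'
#' @param x Numeric levels (used by the fixed rule).
#' @param W Responsibility matrix (used by the weight-based rules).
#' @param truth True component labels.
#' @param rule One of `"fixed"`, `"max_weight"`, `"weight_gap"`.
#' @param sweep Threshold grid; defaults to 101 equal steps over
#'   `[0, 0.25]` for the fixed rule and over `[0, 1]` otherwise.
#' @return A data.frame of class `performance_curve` with columns
#'   `threshold`, `assigned_fraction`, `correct_fraction`, `precision`.
#' @export
performance_curve <- function(x, W = NULL, truth,
                              rule = c("fixed", "max_weight", "weight_gap"),
                              sweep = NULL) {
  rule <- match.arg(rule)
  n <- length(truth)
  if (is.null(sweep)) {
    sweep <- if (rule == "fixed") seq(0, 0.25, length.out = 101)
             else seq(0, 1, length.out = 101)
  }
  N <- C <- numeric(length(sweep))
  for (i in seq_along(sweep)) {
    lab <- switch(rule,
                  fixed = rule_fixed(x, sweep[i]),
                  max_weight = rule_max_weight(W, sweep[i]),
                  weight_gap = rule_weight_gap(W, sweep[i]))
    nc <- evaluate_rule(lab, truth)
    N[i] <- nc[["N"]]
    C[i] <- nc[["C"]]
  }
  out <- data.frame(threshold = sweep,
                    assigned_fraction = N / n,
                    correct_fraction = C / n,
                    precision = ifelse(N > 0, C / N, NA_real_))
  class(out) <- c("performance_curve", "data.frame")
  out
}

#' Signed area between two performance curves
#'
#' Integrates the difference of the two curves' correct fractions as
#' functions of the assigned fraction, over the overlap of their ranges:
#' both curves are linearly interpolated onto the union of their
#' assigned-fraction grids restricted to the common range, and the
#' trapezoid rule is applied to `y_A - y_B`.  Positive values mean curve
#' A (typically the mixture-based rule) dominates curve B (the fixed
#' thresholds).
#'
#' @param curve_a,curve_b [performance_curve()] objects.
#' @return The signed area (a real number); 0 with a warning when the
#'   ranges do not overlap.
#' @export
signed_area_between <- function(curve_a, curve_b) {
  pa <- curve_points(curve_a)
  pb <- curve_points(curve_b)
  lo <- max(min(pa$x), min(pb$x))
  hi <- min(max(pa$x), max(pb$x))
  if (hi <= lo) {
    warning("performance curves share no assigned-fraction range")
    return(0)
  }
  grid <- sort(unique(c(pa$x, pb$x, lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  ya <- stats::approx(pa$x, pa$y, xout = grid, ties = "ordered")$y
  yb <- stats::approx(pb$x, pb$y, xout = grid, ties = "ordered")$y
  d <- ya - yb
  sum((d[-1] + d[-length(d)]) / 2 * diff(grid))
}

# Distinct (assigned_fraction, correct_fraction) points, x ascending.
# Along a sweep equal N implies an identical assignment set, hence equal
# C, so duplicated x carry duplicated y and can be dropped.
curve_points <- function(curve) {
  stopifnot(inherits(curve, "performance_curve"))
  x <- curve$assigned_fraction
  y <- curve$correct_fraction
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  keep <- !duplicated(x)
  list(x = x[keep], y = y[keep])
}
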