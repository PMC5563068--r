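test_that("boundary components follow the smallest-shape rules", {
  m <- beta_mixture(rep(1 / 3, 3), alpha = c(0.5, 3, 2),
                    beta = c(2, 3, 0.5), sort = FALSE)
  expect_equal(unname(boundary_components(m)), c(1, 3))
  m1 <- beta_mixture(1, 1, 1, sort = FALSE)
  expect_equal(unname(boundary_components(m1)), c(1, 1))
  # tie on alpha resolved towards the larger beta
  m2 <- beta_mixture(c(0.5, 0.5), alpha = c(0.5, 0.5), beta = c(2, 5),
                     sort = FALSE)
  expect_equal(unname(boundary_components(m2))[1], 2)
  expect_equal(unname(boundary_components(m2))[2], 1)
  # full tie: lowest index
  m3 <- beta_mixture(c(0.5, 0.5), alpha = c(1, 1), beta = c(1, 1),
                     sort = FALSE)
  expect_equal(unname(boundary_components(m3)), c(1, 1))
})

test_that("E-step yields posterior rows, boundary indicators, weights", {
  x <- c(0.2, 0.5, 0.8)
  es <- e_step(x, beta_mixture(1, 2, 2, sort = FALSE))
  expect_equal(es$W, matrix(1, 3, 1))
  expect_equal(es$pi_plus, 1)

  twin <- beta_mixture(c(0.5, 0.5), c(2, 2), c(2, 2), sort = FALSE)
  es <- e_step(x, twin)
  expect_equal(es$W, matrix(0.5, 3, 2))

  m <- beta_mixture(c(0.4, 0.6), c(0.5, 2), c(2, 0.5), sort = FALSE)
  es <- e_step(c(0, 1, 0.5), m)
  expect_equal(es$W[1, ], c(1, 0))   # x = 0 owned by smallest alpha
  expect_equal(es$W[2, ], c(0, 1))   # x = 1 owned by smallest beta
  expect_equal(rowSums(es$W), rep(1, 3))
  expect_equal(es$pi_plus, colMeans(es$W))

  # interior rows match direct Bayes evaluation
  d1 <- 0.4 * stats::dbeta(0.5, 0.5, 2)
  d2 <- 0.6 * stats::dbeta(0.5, 2, 0.5)
  expect_equal(es$W[3, ], c(d1, d2) / (d1 + d2))
})

test_that("MM-step computes responsibility-weighted moments", {
  x <- c(0.2, 0.4, 0.6)
  W <- matrix(1, 3, 1)
  m <- mm_step(x, W, colMeans(W))
  mom <- params_to_moments(beta_params(m$alpha, m$beta))
  expect_equal(mom$mean, 0.4)
  expect_equal(mom$variance, (0.04 + 0 + 0.04) / 3)

  # hand evaluation with a half-weight component
  x <- c(0.1, 0.3, 0.7, 0.9)
  W <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  m <- mm_step(x, W, colMeans(W))
  mu1 <- params_to_moments(beta_params(m$alpha[1], m$beta[1]))$mean
  expect_equal(mu1, 0.2)

  # single component on the 20-point fixture: one-shot moment fit
  x <- toy_data()
  m <- mm_step(x, matrix(1, 20, 1), 1)
  phi <- 0.0275 * 0.9725 / 0.00116875 - 1
  expect_equal(m$alpha, 0.0275 * phi)
  expect_equal(m$beta, 0.9725 * phi)
})

test_that("components with vanishing weight are dropped", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  W <- cbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  m <- mm_step(x, W, colMeans(W))
  expect_equal(m$c, 1L)
  expect_equal(attr(m, "dropped"), 2L)
  expect_equal(m$weights, 1)
})

test_that("relative change follows the stationarity definition", {
  expect_equal(relative_change(0.5, 0.5), 0)
  expect_equal(relative_change(0, 0), 0)
  expect_equal(relative_change(1.0, 1.1), 0.1 / 1.1)
  expect_equal(relative_change(c(1, 0), c(2, 0)), c(0.5, 0))
})

test_that("partition initialization spreads components over the interval", {
  # c = 1: plain sample moments
  x <- c(0.2, 0.4, 0.6)
  m <- init_partition(x, 1)
  expect_equal(params_to_moments(beta_params(m$alpha, m$beta))$mean, 0.4)

  # three clusters -> three components whose moments are the sample
  # moments of the (overlapping) windows [0, 0.5], [0, 1], [0.5, 1],
  # with weights proportional to the window point counts
  set.seed(33)
  x <- c(stats::runif(10, 0, 0.05), stats::runif(10, 0.45, 0.55),
         stats::runif(10, 0.95, 1))
  m <- init_partition(x, 3)
  expect_equal(m$c, 3L)
  mu <- m$alpha / (m$alpha + m$beta)
  windows <- list(c(0, 0.5), c(0, 1), c(0.5, 1))
  want_mu <- vapply(windows,
                    function(w) mean(x[x >= w[1] & x <= w[2]]), numeric(1))
  want_n <- vapply(windows,
                   function(w) sum(x >= w[1] & x <= w[2]), numeric(1))
  expect_equal(mu, want_mu, tolerance = 1e-6)
  expect_equal(m$weights, want_n / sum(want_n))

  # an empty window drops its component: with c = 5 the centers sit at
  # multiples of 0.25 and the window around 0.5 is [0.25, 0.75], which
  # boundary-clustered data leaves empty (for c = 3 every window spans
  # at least half the interval, so removal cannot fire)
  x <- c(stats::runif(10, 0, 0.05), stats::runif(10, 0.95, 1))
  m <- init_partition(x, 5)
  expect_equal(m$c, 4L)

  # c = 2 symmetry break: the two components must differ
  x <- stats::runif(30)
  m <- init_partition(x, 2)
  expect_true(m$alpha[1] != m$alpha[2] || m$beta[1] != m$beta[2])
})

test_that("D2-weighted initialization seeds centers like k-means++", {
  # only one completion exists
  x <- c(rep(0, 5), rep(1, 5))
  for (s in 1:5) {
    m <- init_d2_weighted(x, 2, seed = s)
    expect_equal(m$c, 2L)
  }
  expect_error(init_d2_weighted(c(0.5, 0.5), 3), "distinct")

  # three distinct values, two centers: the center-set distribution has
  # the closed form P({0,1}) = (2 * 0.8 + 1)/ 3 ... computed by
  # enumerating the greedy D^2 draw:
  #   first uniform over {0, 0.5, 1}; D^2 weights give
  #   P({0,1}) = 1/3 (0.8 + 0.8 + 0) + 1/3 * ... ; numerically:
  p01 <- (0.8 + 0.8 + 0) / 3          # first 0 or 1, or never
  p_mid <- (0.2 + 0 + 0.5) / 3        # {0, 0.5}: first 0 (0.2) or 0.5 (0.5)
  expect_equal(p01 + 2 * p_mid, 1)
  x <- c(0, 0.5, 1)
  sets <- vapply(1:1500, function(s) {
    m <- init_d2_weighted(x, 2, seed = s)
    mu <- sort(m$alpha / (m$alpha + m$beta))
    # identify which centers were chosen by the component windows:
    # window [y-0.5, y+0.5] of center 0 has mean of {0, 0.5}, etc.
    paste(round(mu, 3), collapse = "/")
  }, character(1))
  freq <- table(sets) / length(sets)
  expect_equal(length(freq), 3L)      # all three center sets occur
  # the {0,1} completion is the most likely one (p ~ 0.53 vs 0.23)
  expect_equal(max(freq), p01, tolerance = 0.05)
})

test_that("methylation initialization estimates three states with shape guards", {
  set.seed(44)
  truth <- beta_mixture(rep(1 / 3, 3), alpha = c(0.3, 50, 8),
                        beta = c(8, 50, 0.3), sort = FALSE)
  x <- sample_mixture(truth, 2000)$values
  m <- init_methylation(x)
  mu <- m$alpha / (m$alpha + m$beta)
  expect_lt(mu[1], 0.15)
  expect_equal(mu[2], 0.5, tolerance = 0.05)
  expect_gt(mu[3], 0.85)
  # oracle: interval sample moments
  sel <- x <= 0.25
  expect_equal(mu[1], mean(x[sel]), tolerance = 1e-6)

  # all data central: outer states fall back to diffuse defaults
  m <- init_methylation(stats::runif(50, 0.3, 0.7))
  expect_equal(c(m$alpha[1], m$beta[1]), c(0.8, 5))
  expect_equal(c(m$alpha[3], m$beta[3]), c(5, 0.8))

  # rising shape in the unmethylated window is forced falling
  x <- c(stats::runif(40, 0.18, 0.24), stats::runif(10, 0.4, 0.6))
  m <- init_methylation(x)
  expect_equal(m$alpha[1], 0.8)
  # mirrored guard for the fully methylated window
  x <- c(stats::runif(10, 0.4, 0.6), stats::runif(40, 0.76, 0.82))
  m <- init_methylation(x)
  expect_equal(m$beta[3], 0.8)
})

test_that("fit recovers known parameters and is robust to boundary data", {
  set.seed(55)
  x <- stats::rbeta(10000, 2, 5)
  f <- betamix_fit(x, 1)
  expect_true(f$converged)
  expect_equal(f$model$alpha, 2, tolerance = 0.1)
  expect_equal(f$model$beta, 5, tolerance = 0.1)

  # 20-point fixture: single-component fit is a one-shot moment fit
  f <- betamix_fit(toy_data(), 1)
  expect_equal(f$iterations, 1L)
  phi <- 0.0275 * 0.9725 / 0.00116875 - 1
  expect_equal(f$model$alpha, 0.0275 * phi)
  expect_equal(f$model$beta, 0.9725 * phi)

  # well-separated three-state mixture, means recovered within 0.02
  # (three-state data, so start from the methylation initialization)
  truth <- beta_mixture(rep(1 / 3, 3),
                        alpha = c(0.05, 0.5, 0.95) * 50,
                        beta = (1 - c(0.05, 0.5, 0.95)) * 50, sort = FALSE)
  set.seed(56)
  x <- sample_mixture(truth, 5000)$values
  f <- betamix_fit(x, 3, init = init_methylation(x))
  expect_equal(f$model$c, 3L)
  mu <- f$model$alpha / (f$model$alpha + f$model$beta)
  expect_equal(mu, c(0.05, 0.5, 0.95), tolerance = 0.02)

  # error shrinks with sample size (component means, fixed truth)
  err <- sapply(c(500, 5000), function(n) {
    set.seed(57)
    x <- sample_mixture(truth, n)$values
    fn <- betamix_fit(x, 3, init = init_methylation(x))
    max(abs(fn$model$alpha / (fn$model$alpha + fn$model$beta) -
              c(0.05, 0.5, 0.95)))
  })
  expect_lt(err[2], err[1])
})

test_that("fitted mixture mean equals the sample mean at every iteration", {
  set.seed(66)
  for (rep in 1:20) {
    smp <- random_boundary_dataset(n = 120)
    f <- betamix_fit(smp$values, 3, init = init_methylation(smp$values))
    expect_lt(max(abs(f$mixture_mean_trace - mean(smp$values))), 1e-10)
  }
})

test_that("responsibility rows sum to one with exact boundary indicators", {
  set.seed(67)
  smp <- random_boundary_dataset(n = 150)
  f <- betamix_fit(smp$values, 3, init = init_methylation(smp$values))
  W <- f$responsibilities
  expect_equal(rowSums(W), rep(1, length(smp$values)), tolerance = 1e-12)
  at0 <- smp$values == 0
  expect_true(all(W[at0, , drop = FALSE] %in% c(0, 1)))
  expect_equal(rowSums(W[at0, , drop = FALSE] == 1), rep(1, sum(at0)))
})

test_that("estimates vary continuously with eps and need no eps at all", {
  # the moment fit accepts the raw zeros (eps = 0) directly, and the
  # perturbation from replacing them by eps shrinks to nothing as
  # eps -> 0 -- the qualitative opposite of ML estimation, which is
  # undefined at 0 and diverges as eps shrinks
  fits <- lapply(c(0, 1e-5, 1e-4, 1e-3, 5e-3), function(eps) {
    x <- toy_data()
    x[x == 0] <- eps
    betamix_fit(x, 1)$model
  })
  alphas <- vapply(fits, function(m) m$alpha, numeric(1))
  betas <- vapply(fits, function(m) m$beta, numeric(1))
  dev_a <- abs(alphas[-1] - alphas[1]) / alphas[1]
  dev_b <- abs(betas[-1] - betas[1]) / betas[1]
  # deviation decreases monotonically towards eps = 0 ...
  expect_true(all(diff(dev_a) > 0))
  expect_true(all(diff(dev_b) > 0))
  # ... is negligible for small eps, and stays bounded over the sweep
  expect_lt(dev_a[2], 0.01)   # eps = 1e-4
  expect_lt(dev_b[2], 0.01)
  expect_lt(max(dev_a, dev_b), 0.5)
})

test_that("fit is invariant to permuting the input", {
  set.seed(77)
  smp <- random_boundary_dataset(n = 100)
  f1 <- betamix_fit(smp$values, 3, init = init_methylation(smp$values))
  xs <- sample(smp$values)
  f2 <- betamix_fit(xs, 3, init = init_methylation(xs))
  expect_equal(f1$model$alpha, f2$model$alpha, tolerance = 1e-9)
  expect_equal(f1$model$beta, f2$model$beta, tolerance = 1e-9)
  expect_equal(f1$model$weights, f2$model$weights, tolerance = 1e-9)
})

test_that("compiled engine and R reference loop agree", {
  # fixed iteration budget: compares the two engines' trajectories
  # before floating-point round-off differences can be amplified by a
  # long (possibly chaotic near-degenerate) iteration history
  set.seed(88)
  cfg8 <- fit_config(tol = 1e-300, max_iterations = 8)
  for (rep in 1:5) {
    smp <- random_boundary_dataset(n = 80)
    init <- init_methylation(smp$values)
    fc <- betamix_fit(smp$values, 3, cfg8, init = init, engine = "cpp")
    fr <- betamix_fit(smp$values, 3, cfg8, init = init, engine = "r")
    expect_equal(fc$iterations, fr$iterations)
    expect_equal(fc$model$alpha, fr$model$alpha, tolerance = 1e-10)
    expect_equal(fc$model$beta, fr$model$beta, tolerance = 1e-10)
    expect_equal(fc$model$weights, fr$model$weights, tolerance = 1e-10)
    expect_equal(fc$mixture_mean_trace, fr$mixture_mean_trace,
                 tolerance = 1e-12)
    expect_equal(fc$responsibilities, fr$responsibilities,
                 tolerance = 1e-10)
  }
  # and to full convergence on a well-conditioned fit
  set.seed(89)
  x <- stats::rbeta(500, 2, 5)
  fc <- betamix_fit(x, 1, engine = "cpp")
  fr <- betamix_fit(x, 1, engine = "r")
  expect_equal(fc$model$alpha, fr$model$alpha, tolerance = 1e-10)
  expect_equal(fc$model$beta, fr$model$beta, tolerance = 1e-10)
  expect_true(fc$converged && fr$converged)
})
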