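#include <Rcpp.h>
using namespace Rcpp;

// Iterated method of moments inner loop.  Mirrors the R reference loop
// (e_step + mm_step + stationarity check) exactly; kept in C++ because the
// simulation benchmarks run tens of thousands of fits.

static void boundary_comps(const std::vector<double>& alpha,
                           const std::vector<double>& beta,
                           int& j0, int& j1) {
  int k = alpha.size();
  j0 = 0; j1 = 0;
  for (int j = 1; j < k; ++j) {
    if (alpha[j] < alpha[j0] ||
        (alpha[j] == alpha[j0] && beta[j] > beta[j0])) j0 = j;
    if (beta[j] < beta[j1] ||
        (beta[j] == beta[j1] && alpha[j] > alpha[j1])) j1 = j;
  }
}

// [[Rcpp::export]]
List fit_engine_cpp(NumericVector x, NumericVector w0, NumericVector a0,
                    NumericVector b0, double tol, int max_iter,
                    double mean_clamp, double var_floor) {
  const int n = x.size();
  int k = w0.size();
  std::vector<double> pi(w0.begin(), w0.end());
  std::vector<double> alpha(a0.begin(), a0.end());
  std::vector<double> beta(b0.begin(), b0.end());

  std::vector<int> kind(n);  // 0 interior, 1 at zero, 2 at one
  std::vector<double> lx(n), l1x(n);  // log(x), log(1-x) for interior points
  for (int i = 0; i < n; ++i) {
    kind[i] = (x[i] == 0.0) ? 1 : (x[i] == 1.0 ? 2 : 0);
    if (kind[i] == 0) { lx[i] = std::log(x[i]); l1x[i] = std::log1p(-x[i]); }
  }

  std::vector<double> W(n * (size_t)k);
  std::vector<double> mean_trace;
  int iterations = 0, n_dropped = 0;
  bool converged = false;
  double max_rel = R_PosInf;

  // log mixture weights + log beta densities, written via the log-gamma
  // normalizer so alpha + beta in the hundreds cannot overflow:
  // log pi_j - lbeta(a_j, b_j) + (a_j - 1) log x + (b_j - 1) log(1 - x)
  auto run_e_step = [&](std::vector<double>& Wm, std::vector<double>& pi_plus) {
    int j0, j1;
    boundary_comps(alpha, beta, j0, j1);
    std::vector<double> cst(k), am1(k), bm1(k), lw(k);
    for (int j = 0; j < k; ++j) {
      cst[j] = (pi[j] > 0.0)
        ? std::log(pi[j]) - R::lbeta(alpha[j], beta[j]) : R_NegInf;
      am1[j] = alpha[j] - 1.0;
      bm1[j] = beta[j] - 1.0;
    }
    std::fill(pi_plus.begin(), pi_plus.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double* row = &Wm[(size_t)i * k];
      if (kind[i] == 1) {
        std::fill(row, row + k, 0.0); row[j0] = 1.0;
      } else if (kind[i] == 2) {
        std::fill(row, row + k, 0.0); row[j1] = 1.0;
      } else {
        double mx = R_NegInf;
        for (int j = 0; j < k; ++j) {
          lw[j] = (pi[j] > 0.0)
            ? cst[j] + am1[j] * lx[i] + bm1[j] * l1x[i]
            : R_NegInf;
          if (lw[j] > mx) mx = lw[j];
        }
        double s = 0.0;
        for (int j = 0; j < k; ++j) { row[j] = std::exp(lw[j] - mx); s += row[j]; }
        for (int j = 0; j < k; ++j) row[j] /= s;
      }
      for (int j = 0; j < k; ++j) pi_plus[j] += row[j];
    }
    for (int j = 0; j < k; ++j) pi_plus[j] /= n;
  };

  for (int it = 1; it <= max_iter; ++it) {
    iterations = it;
    std::vector<double> pi_plus(k);
    run_e_step(W, pi_plus);

    // drop components with vanishing weight, renormalize rows
    std::vector<int> keep;
    for (int j = 0; j < k; ++j) if (pi_plus[j] > 1e-12) keep.push_back(j);
    bool dropped = ((int)keep.size() < k);
    if (keep.empty()) stop("all components lost their weight");
    if (dropped) {
      n_dropped += k - keep.size();
      int k2 = keep.size();
      std::vector<double> W2(n * (size_t)k2);
      std::vector<double> pp2(k2, 0.0);
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < k2; ++j) s += W[(size_t)i * k + keep[j]];
        for (int j = 0; j < k2; ++j) {
          double v = W[(size_t)i * k + keep[j]] / s;
          W2[(size_t)i * k2 + j] = v;
          pp2[j] += v;
        }
      }
      for (int j = 0; j < k2; ++j) pp2[j] /= n;
      std::vector<double> a2(k2), b2(k2);
      for (int j = 0; j < k2; ++j) { a2[j] = alpha[keep[j]]; b2[j] = beta[keep[j]]; }
      k = k2; W.swap(W2); pi_plus.swap(pp2); alpha.swap(a2); beta.swap(b2);
      pi.assign(k, 0.0);
    }

    // MM-step: responsibility-weighted moments -> shape parameters
    std::vector<double> new_a(k), new_b(k), mu(k);
    for (int j = 0; j < k; ++j) {
      double denom = n * pi_plus[j];
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += W[(size_t)i * k + j] * x[i];
      m /= denom;
      double s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        s2 += W[(size_t)i * k + j] * d * d;
      }
      s2 /= denom;
      mu[j] = m;
      double mc = std::min(std::max(m, mean_clamp), 1.0 - mean_clamp);
      double v = std::max(s2, var_floor);
      v = std::min(v, (1.0 - 1e-6) * mc * (1.0 - mc));
      double phi = mc * (1.0 - mc) / v - 1.0;
      new_a[j] = mc * phi;
      new_b[j] = (1.0 - mc) * phi;
    }

    // mixture expectation from the raw weighted moments (before the
    // degeneracy guards): equals the sample mean exactly, by design
    double emean = 0.0;
    for (int j = 0; j < k; ++j) emean += pi_plus[j] * mu[j];
    mean_trace.push_back(emean);

    if (dropped) {
      max_rel = R_PosInf;  // parameter sets not comparable this iteration
      pi = pi_plus; alpha = new_a; beta = new_b;
      continue;
    }
    max_rel = 0.0;
    for (int j = 0; j < k; ++j) {
      double trio_old[3] = {pi[j], alpha[j], beta[j]};
      double trio_new[3] = {pi_plus[j], new_a[j], new_b[j]};
      for (int q = 0; q < 3; ++q) {
        double d = std::max(std::fabs(trio_old[q]), std::fabs(trio_new[q]));
        double rel = (d == 0.0) ? 0.0 : std::fabs(trio_new[q] - trio_old[q]) / d;
        if (rel > max_rel) max_rel = rel;
      }
    }
    pi = pi_plus; alpha = new_a; beta = new_b;
    if (max_rel < tol) { converged = true; break; }
  }

  // final responsibilities under the final parameters
  std::vector<double> pi_fin(k);
  run_e_step(W, pi_fin);
  NumericMatrix Wout(n, k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) Wout(i, j) = W[(size_t)i * k + j];

  return List::create(
    _["weights"] = NumericVector(pi.begin(), pi.end()),
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["W"] = Wout,
    _["iterations"] = iterations,
    _["converged"] = converged,
    _["final_max_relative_change"] = max_rel,
    _["mean_trace"] = NumericVector(mean_trace.begin(), mean_trace.end()),
    _["n_dropped"] = n_dropped);
}
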