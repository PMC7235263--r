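#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Covariance-form cyclical coordinate descent for the elastic-net selection
// index: minimize  -G'beta + (1/2) beta' P beta + lambda * J(beta),
//   J(beta) = (1-alpha)/2 * sum(beta^2) + alpha * sum(|beta|).
// P and G play the roles X'X/(n-1) and X'y/(n-1) play in a phenotypic
// elastic net; no data matrix is ever touched ("covariance updates").
// Solutions are computed along a decreasing lambda grid with warm starts.
// ---------------------------------------------------------------------------

inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_cd_enet(const NumericMatrix& P, const NumericVector& G,
                 const NumericVector& lambdas, double alpha,
                 double tol, int maxit,
                 Nullable<NumericVector> beta_start = R_NilValue) {
  const int p = G.size();
  const int nl = lambdas.size();
  NumericVector beta(p);
  if (beta_start.isNotNull()) {
    NumericVector b0(beta_start);
    for (int j = 0; j < p; ++j) beta[j] = b0[j];
  }
  // c = P %*% beta, maintained incrementally
  NumericVector c(p);
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double bj = beta[j];
      for (int k = 0; k < p; ++k) c[k] += P(k, j) * bj;
    }
  }
  NumericMatrix B(p, nl);
  IntegerVector iters(nl);
  LogicalVector conv(nl);

  std::vector<int> active;
  active.reserve(p);
  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    const double lam1 = lam * alpha;        // L1 part
    const double lam2 = lam * (1.0 - alpha); // L2 part
    int it = 0;
    bool converged = false;
    // full sweeps establish the active set; inner sweeps iterate it to
    // convergence (the usual active-set strategy for coordinate descent)
    while (it < maxit) {
      ++it;
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        const double bj = beta[j];
        const double z = G[j] - c[j] + P(j, j) * bj;
        const double bn = soft(z, lam1) / (P(j, j) + lam2);
        const double d = bn - bj;
        if (d != 0.0) {
          beta[j] = bn;
          for (int k = 0; k < p; ++k) c[k] += P(k, j) * d;
          const double ad = d < 0 ? -d : d;
          if (ad > dmax) dmax = ad;
        }
      }
      if (dmax < tol) { converged = true; break; }
      active.clear();
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      while (it < maxit) {
        ++it;
        double da = 0.0;
        for (int ji = 0; ji < (int)active.size(); ++ji) {
          const int j = active[ji];
          const double bj = beta[j];
          const double z = G[j] - c[j] + P(j, j) * bj;
          const double bn = soft(z, lam1) / (P(j, j) + lam2);
          const double d = bn - bj;
          if (d != 0.0) {
            beta[j] = bn;
            for (int k = 0; k < p; ++k) c[k] += P(k, j) * d;
            const double ad = d < 0 ? -d : d;
            if (ad > da) da = ad;
          }
        }
        if (da < tol) break;
      }
    }
    iters[l] = it;
    conv[l] = converged;
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return List::create(_["beta"] = B, _["iter"] = iters, _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// Profiled REML for the one-factor random model  y_ij = mu + g_j + e_ij,
// g_j ~ iid N(0, s2g), e_ij ~ iid N(0, s2e), mu a fixed intercept.
// Works from sufficient statistics: group sums s_j, group sizes n_j, y'y.
// With phi = s2g/s2e the restricted likelihood profiles to a 1-D criterion
//   f(phi) = (n-1) log(Q/(n-1)) + sum_j log(1 + phi n_j) + log a,
//   a = sum n_j/(1+phi n_j), b = sum s_j/(1+phi n_j),
//   Q = y'y - phi sum s_j^2/(1+phi n_j) - b^2/a,
// minimized by a coarse log-grid scan plus golden-section refinement.
// ---------------------------------------------------------------------------

static double reml1f_crit(double phi, double yty,
                          const NumericVector& s, const NumericVector& nj,
                          int n, double* Q_out) {
  const int g = s.size();
  double a = 0.0, b = 0.0, q2 = 0.0, ld = 0.0;
  for (int j = 0; j < g; ++j) {
    const double den = 1.0 + phi * nj[j];
    a += nj[j] / den;
    b += s[j] / den;
    q2 += s[j] * s[j] / den;
    ld += std::log(den);
  }
  double Q = yty - phi * q2 - b * b / a;
  if (Q < 1e-300) Q = 1e-300;
  if (Q_out) *Q_out = Q;
  return (n - 1) * std::log(Q / (n - 1)) + ld + std::log(a);
}

// derivative of the profiled criterion with respect to phi; its sign change
// locates the optimum without comparing nearly-equal criterion values (this
// keeps the estimator exactly equivariant under exact rescalings of y)
static double reml1f_dcrit(double phi, double yty,
                           const NumericVector& s, const NumericVector& nj,
                           int n) {
  const int g = s.size();
  double a = 0.0, b = 0.0, q2 = 0.0, da = 0.0, db = 0.0, dq2 = 0.0;
  for (int j = 0; j < g; ++j) {
    const double den = 1.0 + phi * nj[j];
    const double den2 = den * den;
    a += nj[j] / den;
    b += s[j] / den;
    q2 += s[j] * s[j] / den;
    da -= nj[j] * nj[j] / den2;
    db -= s[j] * nj[j] / den2;
    dq2 -= s[j] * s[j] * nj[j] / den2;
  }
  double Q = yty - phi * q2 - b * b / a;
  if (Q < 1e-300) Q = 1e-300;
  const double dQ = -q2 - phi * dq2 - (2.0 * b * db * a - b * b * da) / (a * a);
  return (n - 1) * dQ / Q + a + da / a;
}

// [[Rcpp::export]]
NumericVector cpp_reml1f(double yty, const NumericVector& s,
                         const NumericVector& nj, int n) {
  // locate a sign change of the derivative on a log(phi) grid, then bisect
  const double tlo = -18.0, thi = 18.0;
  const int ngrid = 73;
  double phi_hat;
  if (reml1f_dcrit(0.0, yty, s, nj, n) >= 0.0) {
    phi_hat = 0.0;                     // criterion increasing at the boundary
  } else {
    double t_neg = R_NegInf, t_pos = R_PosInf;
    for (int i = 0; i < ngrid; ++i) {
      const double t = tlo + (thi - tlo) * i / (ngrid - 1);
      const double d = reml1f_dcrit(std::exp(t), yty, s, nj, n);
      if (d < 0.0) t_neg = t;
      else { t_pos = t; break; }
    }
    if (!R_FINITE(t_pos)) {
      phi_hat = std::exp(thi);         // still decreasing: residual ~ 0
    } else {
      double lo = R_FINITE(t_neg) ? t_neg : tlo - 18.0;
      double hi = t_pos;
      for (int it = 0; it < 90; ++it) {
        const double mid = 0.5 * (lo + hi);
        if (reml1f_dcrit(std::exp(mid), yty, s, nj, n) < 0.0) lo = mid;
        else hi = mid;
      }
      phi_hat = std::exp(0.5 * (lo + hi));
      // guard against a local dip: boundary must not beat the interior point
      if (reml1f_crit(0.0, yty, s, nj, n, 0) <
          reml1f_crit(phi_hat, yty, s, nj, n, 0))
        phi_hat = 0.0;
    }
  }
  double Q;
  const double fopt = reml1f_crit(phi_hat, yty, s, nj, n, &Q);
  const double s2e = Q / (n - 1);
  const double s2g = phi_hat * s2e;
  const double loglik = -0.5 * (fopt + (n - 1) * (1.0 + std::log(2.0 * M_PI)));
  return NumericVector::create(s2g, s2e, loglik, phi_hat);
}

// Column-wise REML over a matrix of responses sharing one grouping factor.
// S: g x p matrix of per-group sums; yty: length-p vector of y'y.
// [[Rcpp::export]]
NumericMatrix cpp_reml1f_multi(const NumericVector& yty, const NumericMatrix& S,
                               const NumericVector& nj, int n) {
  const int p = yty.size();
  NumericMatrix out(4, p);
  const int g = S.nrow();
  NumericVector s(g);
  for (int c = 0; c < p; ++c) {
    for (int j = 0; j < g; ++j) s[j] = S(j, c);
    NumericVector r = cpp_reml1f(yty[c], s, nj, n);
    for (int k = 0; k < 4; ++k) out(k, c) = r[k];
  }
  return out;
}
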