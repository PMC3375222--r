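// Compiled kernels: greedy pairwise-identity filtering of fragment sets and
// an SMO solver for the C-SVC with RBF kernel (maximal-violating-pair
// working-set selection with second-order tie refinement, as in libsvm).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Greedy keep-first filter: row i is kept iff its positional identity with
// every previously kept row is < threshold. Rows are integer-encoded
// fragments (same length). Early exit once the match count reaches the
// minimum that would violate the bound.
// [[Rcpp::export]]
LogicalVector greedy_identity_filter(IntegerMatrix frags, double threshold) {
  const int n = frags.nrow(), w = frags.ncol();
  const int limit = (int)std::ceil(threshold * w);  // matches >= limit => drop
  LogicalVector keep(n);
  std::vector<int> kept;
  kept.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t j = 0; j < kept.size() && ok; ++j) {
      const int r = kept[j];
      int matches = 0;
      for (int p = 0; p < w; ++p) {
        if (frags(i, p) == frags(r, p) && ++matches >= limit) { ok = false; break; }
      }
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}

// ---------------------------------------------------------------------------
// RBF C-SVC via SMO.
// Solves  min_a  0.5 a'Qa - e'a   s.t. 0 <= a_i <= C, y'a = 0,
// with Q_ij = y_i y_j exp(-gamma ||x_i - x_j||^2).

// copy an R column-major matrix into a contiguous row-major buffer so
// row dot products stream through cache
static std::vector<double> row_major(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> M((size_t)n * d);
  for (int p = 0; p < d; ++p)
    for (int i = 0; i < n; ++i) M[(size_t)i * d + p] = X(i, p);
  return M;
}

// [[Rcpp::export]]
List svc_smo_fit(NumericMatrix X, NumericVector y, double C, double gamma,
                 double eps = 1e-3, int max_iter = 0) {
  const int n = X.nrow(), d = X.ncol();
  if (max_iter <= 0) max_iter = std::max(10000000, 100 * n);
  const std::vector<double> Xr = row_major(X);
  std::vector<double> sqnorm(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    double s = 0.0;
    for (int p = 0; p < d; ++p) s += xi[p] * xi[p];
    sqnorm[i] = s;
  }

  // full kernel matrix; training sets here are a few thousand rows at most
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    const double* xi = &Xr[(size_t)i * d];
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &Xr[(size_t)j * d];
      double dot = 0.0;
      for (int p = 0; p < d; ++p) dot += xi[p] * xj[p];
      double dist2 = sqnorm[i] + sqnorm[j] - 2.0 * dot;
      if (dist2 < 0) dist2 = 0;
      const double v = std::exp(-gamma * dist2);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G_i = (Qa)_i - 1
  const double tau = 1e-12;
  int iter = 0;

  for (; iter < max_iter; ++iter) {
    // working-set selection
    int i = -1;
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up) {
        const double v = -y[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
    }
    if (i < 0) break;
    int j = -1;
    double obj_min = 1e30;
    const double* Ki = &K[(size_t)i * n];
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      const double v = -y[t] * G[t];
      if (v < gmin) gmin = v;
      const double b = gmax + y[t] * G[t];
      if (b > 0) {
        double a = 2.0 - 2.0 * y[i] * y[t] * Ki[t];  // K_ii = K_tt = 1 (RBF)
        if (a <= 0) a = tau;
        const double obj = -(b * b) / a;
        if (obj < obj_min) { obj_min = obj; j = t; }
      }
    }
    if (gmax - gmin < eps || j == -1) break;

    // analytic update of (alpha_i, alpha_j)
    const double* Kj = &K[(size_t)j * n];
    double a = 2.0 - 2.0 * y[i] * y[j] * Ki[j];
    if (a <= 0) a = tau;
    const double b = gmax + y[j] * G[j];
    double di = y[i] * b / a, dj = -y[j] * b / a;  // change in alpha

    double ai = alpha[i] + di, aj = alpha[j] + dj;
    // clip to the box along the constraint y_i da_i + y_j da_j = 0
    const double s = y[i] * y[j];
    if (ai > C) { aj += s * (ai - C); ai = C; }
    else if (ai < 0) { aj += s * ai; ai = 0; }
    if (aj > C) { ai += s * (aj - C); aj = C; }
    else if (aj < 0) { ai += s * aj; aj = 0; }
    if (ai > C) ai = C; else if (ai < 0) ai = 0;

    const double dai = ai - alpha[i], daj = aj - alpha[j];
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
  }

  // rho from free support vectors (fallback: midpoint of the bounds)
  double rho_sum = 0.0; int nfree = 0;
  double ub = 1e30, lb = -1e30;
  for (int t = 0; t < n; ++t) {
    const double yg = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { rho_sum += yg; ++nfree; }
    const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up) ub = std::min(ub, yg);
    if (low) lb = std::max(lb, yg);
  }
  const double rho = nfree > 0 ? rho_sum / nfree : (ub + lb) / 2.0;

  // keep only support vectors
  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 0) sv.push_back(t);
  NumericMatrix SV((int)sv.size(), X.ncol());
  NumericVector coef((int)sv.size());
  for (size_t s2 = 0; s2 < sv.size(); ++s2) {
    coef[s2] = alpha[sv[s2]] * y[sv[s2]];
    for (int p = 0; p < X.ncol(); ++p) SV((int)s2, p) = X(sv[s2], p);
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["iterations"] = iter, _["n_sv"] = (int)sv.size(),
                      _["converged"] = iter < max_iter);
}

// decision values f(x) = sum_s coef_s K(sv_s, x) - rho
// [[Rcpp::export]]
NumericVector svc_decision(NumericMatrix SV, NumericVector coef, double rho,
                           double gamma, NumericMatrix X) {
  const int m = SV.nrow(), n = X.nrow(), d = X.ncol();
  const std::vector<double> Sr = row_major(SV), Xr = row_major(X);
  std::vector<double> svn(m), xn(n);
  for (int s = 0; s < m; ++s) {
    const double* v = &Sr[(size_t)s * d];
    double t = 0; for (int p = 0; p < d; ++p) t += v[p] * v[p];
    svn[s] = t;
  }
  for (int i = 0; i < n; ++i) {
    const double* v = &Xr[(size_t)i * d];
    double t = 0; for (int p = 0; p < d; ++p) t += v[p] * v[p];
    xn[i] = t;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    double f = -rho;
    for (int s = 0; s < m; ++s) {
      const double* sv = &Sr[(size_t)s * d];
      double dot = 0;
      for (int p = 0; p < d; ++p) dot += sv[p] * xi[p];
      double dist2 = svn[s] + xn[i] - 2.0 * dot;
      if (dist2 < 0) dist2 = 0;
      f += coef[s] * std::exp(-gamma * dist2);
    }
    out[i] = f;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour distances for the KNN encoding.
// Fragments are integer-encoded rows; dist(a, b) = mean_p (1 - sim(a_p, b_p))
// with `sim` the normalized 21x21 similarity matrix.

// [[Rcpp::export]]
NumericMatrix fragment_distance_matrix(IntegerMatrix A, IntegerMatrix B,
                                       NumericMatrix sim) {
  const int na = A.nrow(), nb = B.nrow(), w = A.ncol();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int p = 0; p < w; ++p)
        s += 1.0 - sim(A(i, p) - 1, B(j, p) - 1);
      D(i, j) = s / w;
    }
  return D;
}
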