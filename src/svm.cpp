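// C-SVC with an RBF kernel, trained by Platt's SMO with an error cache.
// Labels enter as +1/-1; the fit returns alpha*y coefficients and the bias,
// and prediction returns raw decision values (distance-to-margin scale).
// Probability calibration (Platt scaling) happens on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct SMO {
  const std::vector<std::vector<double>>& K;
  const std::vector<double>& y;
  double C, tol, eps;
  int n;
  std::vector<double> alpha, error;
  double b;
  std::mt19937 rng;

  SMO(const std::vector<std::vector<double>>& K_,
      const std::vector<double>& y_, double C_, double tol_, int seed)
    : K(K_), y(y_), C(C_), tol(tol_), eps(1e-8), n((int)y_.size()),
      alpha(n, 0.0), error(n), b(0.0), rng((unsigned)seed) {
    for (int i = 0; i < n; ++i) error[i] = -y[i]; // f(x)=0 initially
  }

  double f(int i) const {
    double s = -b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0) s += alpha[j] * y[j] * K[i][j];
    return s;
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = error[i1], E2 = error[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a1 + a2 - C); H = std::min(C, a1 + a2); }
    if (L >= H) return false;
    double k11 = K[i1][i1], k12 = K[i1][i2], k22 = K[i2][i2];
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // objective at clip bounds
      double f1 = y1 * E1 - a1 * k11 - s * a2 * k12;
      double f2 = y2 * E2 - a2 * k22 - s * a1 * k12;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps) a2new = L;
      else if (objL > objH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);

    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > 0 && a1new < C) bnew = b1;
    else if (a2new > 0 && a2new < C) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int k = 0; k < n; ++k)
      error[k] += d1 * K[i1][k] + d2 * K[i2][k] - db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = error[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximize |E1 - E2| over non-bound alphas
      int best = -1;
      double bestgap = 0.0;
      for (int i = 0; i < n; ++i)
        if (alpha[i] > 0 && alpha[i] < C) {
          double gap = std::fabs(error[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      if (best >= 0 && take_step(best, i2)) return true;
      // heuristic 2: loop over non-bound, then all, from random start
      std::uniform_int_distribution<int> d(0, n - 1);
      int start = d(rng);
      for (int k = 0; k < n; ++k) {
        int i = (start + k) % n;
        if (alpha[i] > 0 && alpha[i] < C && take_step(i, i2)) return true;
      }
      start = d(rng);
      for (int k = 0; k < n; ++k) {
        int i = (start + k) % n;
        if (take_step(i, i2)) return true;
      }
    }
    return false;
  }

  void solve(int max_sweeps) {
    int num_changed = 0;
    bool examine_all = true;
    int sweeps = 0;
    while ((num_changed > 0 || examine_all) && sweeps < max_sweeps) {
      ++sweeps;
      num_changed = 0;
      for (int i = 0; i < n; ++i) {
        if (examine_all || (alpha[i] > 0 && alpha[i] < C))
          if (examine(i)) ++num_changed;
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
    }
  }
};

std::vector<std::vector<double>> rbf_matrix(const NumericMatrix& X,
                                            double gamma) {
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double>> K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    K[i][i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int f = 0; f < p; ++f) {
        double t = X(i, f) - X(j, f);
        d += t * t;
      }
      K[i][j] = K[j][i] = std::exp(-gamma * d);
    }
  }
  return K;
}

} // namespace

// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_sweeps, int seed) {
  int n = X.nrow();
  std::vector<double> yy(y.begin(), y.end());
  auto K = rbf_matrix(X, gamma);
  SMO smo(K, yy, C, tol, seed);
  smo.solve(max_sweeps);
  // keep only support vectors
  std::vector<int> sv;
  for (int i = 0; i < n; ++i)
    if (smo.alpha[i] > 1e-12) sv.push_back(i);
  int m = (int)sv.size();
  NumericMatrix SV(m, X.ncol());
  NumericVector coef(m);
  for (int k = 0; k < m; ++k) {
    for (int f = 0; f < X.ncol(); ++f) SV(k, f) = X(sv[k], f);
    coef[k] = smo.alpha[sv[k]] * yy[sv[k]];
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["b"] = smo.b,
                      _["gamma"] = gamma);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix SV, NumericVector coef, double b,
                               double gamma, NumericMatrix X) {
  int n = X.nrow(), m = SV.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = -b;
    for (int k = 0; k < m; ++k) {
      double d = 0.0;
      for (int f = 0; f < p; ++f) {
        double t = X(i, f) - SV(k, f);
        d += t * t;
      }
      s += coef[k] * std::exp(-gamma * d);
    }
    out[i] = s;
  }
  return out;
}
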