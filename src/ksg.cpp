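// Kraskov-Stogbauer-Grassberger (KSG, algorithm 1) k-nearest-neighbor
// estimators of mutual information and conditional mutual information in the
// max-norm, plus a batched driver that fills pairwise TE/MI matrices for a
// panel of time series. Estimates are in nats. Brute-force neighbor search:
// the panel sizes used here (<= a few thousand samples) keep O(N^2) cheap
// and exactly deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double psi(double v) { return R::digamma(v); }

// distance to k-th nearest neighbor of point i in the joint space given by
// columns (pointers) in `dims`
static double kth_joint_dist(const std::vector<const double*>& dims, int n,
                             int i, int k, std::vector<double>& buf) {
  buf.clear();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double d = 0.0;
    for (const double* col : dims) {
      double dd = std::fabs(col[i] - col[j]);
      if (dd > d) d = dd;
    }
    buf.push_back(d);
  }
  std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
  return buf[k - 1];
}

static int count_within(const std::vector<const double*>& dims, int n, int i,
                        double eps) {
  int cnt = 0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double d = 0.0;
    for (const double* col : dims) {
      double dd = std::fabs(col[i] - col[j]);
      if (dd > d) d = dd;
    }
    if (d < eps) ++cnt;
  }
  return cnt;
}

static double ksg_mi_core(const double* x, const double* y, int n, int k) {
  std::vector<const double*> joint = {x, y}, dx = {x}, dy = {y};
  std::vector<double> buf;
  buf.reserve(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double eps = kth_joint_dist(joint, n, i, k, buf);
    if (eps <= 0) {
      // duplicated joint points: count exact ties as within
      eps = std::numeric_limits<double>::min();
    }
    int nx = count_within(dx, n, i, eps);
    int ny = count_within(dy, n, i, eps);
    acc += psi(nx + 1.0) + psi(ny + 1.0);
  }
  return psi((double)k) + psi((double)n) - acc / n;
}

// CMI(X; Y | Z), Frenzel-Pompe form of KSG
static double ksg_cmi_core(const double* x, const double* y, const double* z,
                           int n, int k) {
  std::vector<const double*> joint = {x, y, z}, dxz = {x, z}, dyz = {y, z},
                             dz = {z};
  std::vector<double> buf;
  buf.reserve(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double eps = kth_joint_dist(joint, n, i, k, buf);
    if (eps <= 0) eps = std::numeric_limits<double>::min();
    int nxz = count_within(dxz, n, i, eps);
    int nyz = count_within(dyz, n, i, eps);
    int nz = count_within(dz, n, i, eps);
    acc += psi(nxz + 1.0) + psi(nyz + 1.0) - psi(nz + 1.0);
  }
  return psi((double)k) - acc / n;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  return ksg_mi_core(REAL(x), REAL(y), n, k);
}

// [[Rcpp::export]]
double ksg_cmi_cpp(NumericVector x, NumericVector y, NumericVector z, int k) {
  int n = x.size();
  return ksg_cmi_core(REAL(x), REAL(y), REAL(z), n, k);
}

// Pairwise TE (source j -> target i, history lengths l = k = 1) and MI over
// the columns of X. te[j, i] = TE(col j -> col i); mi symmetric.
// [[Rcpp::export]]
List pairwise_te_mi_cpp(NumericMatrix X, int k_neighbors, bool compute_mi) {
  int n = X.nrow(), p = X.ncol();
  int m = n - 1; // embedded length
  NumericMatrix te(p, p), mi(p, p);
  // build lagged views
  std::vector<std::vector<double>> fut(p), past(p);
  for (int c = 0; c < p; ++c) {
    fut[c].assign(X.begin() + c * n + 1, X.begin() + c * n + n);
    past[c].assign(X.begin() + c * n, X.begin() + c * n + n - 1);
  }
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) {
      if (i == j) continue;
      te(j, i) = ksg_cmi_core(fut[i].data(), past[j].data(), past[i].data(),
                              m, k_neighbors);
    }
    if (compute_mi) {
      for (int j = i + 1; j < p; ++j) {
        double v = ksg_mi_core(&X(0, i), &X(0, j), n, k_neighbors);
        mi(i, j) = v;
        mi(j, i) = v;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["te"] = te, _["mi"] = mi);
}
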