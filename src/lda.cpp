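#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// In-place Cholesky factorization A = L L^T (k x k, col-major, lower
// triangle). Returns false if A is not positive definite (singular
// scatter with ridge = 0).
static bool chol_factor(std::vector<double>& A, int k) {
  for (int j = 0; j < k; ++j) {
    double d = A[j + j * k];
    for (int p = 0; p < j; ++p) d -= A[j + p * k] * A[j + p * k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j + j * k] = d;
    for (int i = j + 1; i < k; ++i) {
      double s = A[i + j * k];
      for (int p = 0; p < j; ++p) s -= A[i + p * k] * A[j + p * k];
      A[i + j * k] = s / d;
    }
  }
  return true;
}

// solve L L^T x = b given the factor from chol_factor
static void chol_solve_factored(const std::vector<double>& L,
                                const double* b, double* x, int k) {
  for (int i = 0; i < k; ++i) {
    double s = b[i];
    for (int p = 0; p < i; ++p) s -= L[i + p * k] * x[p];
    x[i] = s / L[i + i * k];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = x[i];
    for (int p = i + 1; p < k; ++p) s -= L[p + i * k] * x[p];
    x[i] = s / L[i + i * k];
  }
}

static bool chol_solve(std::vector<double>& A, const double* b, double* x,
                       int k) {
  if (!chol_factor(A, k)) return false;
  chol_solve_factored(A, b, x, k);
  return true;
}

struct SubsetStats {
  int n, k, n1, n0;
  std::vector<double> Xs;   // N x k, col-major
  std::vector<double> s1, s0, S;  // class sums (k), total crossprod (k x k)
};

static void compute_stats(const NumericMatrix& X, const IntegerVector& y,
                          const int* cols, int k, SubsetStats& st) {
  const int n = X.nrow();
  st.n = n; st.k = k;
  st.Xs.assign((size_t)n * k, 0.0);
  st.s1.assign(k, 0.0);
  st.s0.assign(k, 0.0);
  st.S.assign((size_t)k * k, 0.0);
  st.n1 = 0;
  for (int i = 0; i < n; ++i) st.n1 += y[i];
  st.n0 = n - st.n1;
  for (int j = 0; j < k; ++j) {
    const double* src = &X(0, cols[j]);
    double* dst = &st.Xs[(size_t)j * n];
    std::copy(src, src + n, dst);
    double a1 = 0.0, a0 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (y[i]) a1 += dst[i]; else a0 += dst[i];
    }
    st.s1[j] = a1; st.s0[j] = a0;
  }
  for (int j = 0; j < k; ++j) {
    for (int l = j; l < k; ++l) {
      double s = 0.0;
      const double* cj = &st.Xs[(size_t)j * st.n];
      const double* cl = &st.Xs[(size_t)l * st.n];
      for (int i = 0; i < st.n; ++i) s += cj[i] * cl[i];
      st.S[j + l * k] = s;
      st.S[l + j * k] = s;
    }
  }
}

// Fit on all samples; fill w (k) and b. Returns false if singular.
static bool fit_full(const SubsetStats& st, double ridge, bool empirical,
                     std::vector<double>& w, double& b,
                     std::vector<double>& A, std::vector<double>& m1,
                     std::vector<double>& m0, std::vector<double>& dm) {
  const int k = st.k;
  for (int j = 0; j < k; ++j) {
    m1[j] = st.s1[j] / st.n1;
    m0[j] = st.s0[j] / st.n0;
    dm[j] = m1[j] - m0[j];
  }
  for (int j = 0; j < k; ++j)
    for (int l = 0; l < k; ++l)
      A[j + l * k] = st.S[j + l * k] - st.n1 * m1[j] * m1[l]
        - st.n0 * m0[j] * m0[l];
  for (int j = 0; j < k; ++j) A[j + j * k] += ridge;
  if (!chol_solve(A, dm.data(), w.data(), k)) return false;
  double mid = 0.0;
  for (int j = 0; j < k; ++j) mid += w[j] * (m1[j] + m0[j]);
  b = -0.5 * mid;
  if (empirical) b += std::log((double)st.n1 / st.n0);
  return true;
}

// [[Rcpp::export]]
NumericVector lda_loocv_cpp(NumericMatrix X, IntegerVector y, double ridge,
                            bool empirical) {
  const int n = X.nrow(), k = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  std::vector<int> cols(k);
  for (int j = 0; j < k; ++j) cols[j] = j;
  SubsetStats st;
  compute_stats(X, y, cols.data(), k, st);
  if (st.n1 < 2 || st.n0 < 2)
    stop("each class needs at least 2 samples for LOOCV");
  NumericVector out(n);
  std::vector<double> xi(k), m1(k), m0(k), dm(k), w(k),
    A((size_t)k * k);
  for (int i = 0; i < n; ++i) {
    const int yi = y[i];
    const int n1f = st.n1 - yi, n0f = st.n0 - (1 - yi);
    for (int j = 0; j < k; ++j) {
      xi[j] = st.Xs[i + (size_t)j * n];
      const double s1f = st.s1[j] - yi * xi[j];
      const double s0f = st.s0[j] - (1 - yi) * xi[j];
      m1[j] = s1f / n1f;
      m0[j] = s0f / n0f;
      dm[j] = m1[j] - m0[j];
    }
    for (int j = 0; j < k; ++j)
      for (int l = 0; l < k; ++l)
        A[j + l * k] = st.S[j + l * k] - xi[j] * xi[l]
          - n1f * m1[j] * m1[l] - n0f * m0[j] * m0[l];
    for (int j = 0; j < k; ++j) A[j + j * k] += ridge;
    if (!chol_solve(A, dm.data(), w.data(), k))
      stop("singular within-class scatter in a LOOCV fold; "
           "use a positive ridge");
    double mid = 0.0, sc = 0.0;
    for (int j = 0; j < k; ++j) {
      mid += w[j] * (m1[j] + m0[j]);
      sc += w[j] * xi[j];
    }
    double b = -0.5 * mid;
    if (empirical) b += std::log((double)n1f / n0f);
    out[i] = sc + b;
  }
  return out;
}

// Mann-Whitney AUC with ties counted 1/2, via midranks.
static double auc_from_scores(const std::vector<double>& s,
                              const IntegerVector& y) {
  const int n = (int)s.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[idx[j + 1]] == s[idx[i]]) ++j;
    const double mid = 0.5 * (i + j) + 1.0;  // midrank (1-based)
    for (int p = i; p <= j; ++p) rank[idx[p]] = mid;
    i = j + 1;
  }
  double rsum = 0.0;
  int n1 = 0;
  for (int p = 0; p < n; ++p) {
    if (y[p]) { rsum += rank[p]; ++n1; }
  }
  const int n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}

// [[Rcpp::export]]
NumericVector auc_cpp(NumericVector scores, IntegerVector y) {
  std::vector<double> s(scores.begin(), scores.end());
  return NumericVector::create(auc_from_scores(s, y));
}

// Evaluate many feature subsets at once: LOOCV accuracy (fraction of
// held-out samples whose score sign matches the label; ties at 0 are
// called control) and training AUC of the full-data fit, used for
// rank tie-breaking in the beam search.
// subsets: list of 0-based integer column index vectors.
// [[Rcpp::export]]
NumericMatrix beam_eval_cpp(NumericMatrix X, IntegerVector y, List subsets,
                            double ridge, bool empirical) {
  const int n = X.nrow();
  const int m = subsets.size();
  NumericMatrix out(m, 2);
  colnames(out) = CharacterVector::create("loocv_accuracy",
                                          "training_auc");
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[i];
  if (n1 < 2 || n - n1 < 2)
    stop("each class needs at least 2 samples for LOOCV");

  for (int s = 0; s < m; ++s) {
    IntegerVector sub = subsets[s];
    const int k = sub.size();
    std::vector<int> cols(sub.begin(), sub.end());
    SubsetStats st;
    compute_stats(X, y, cols.data(), k, st);

    std::vector<double> xi(k), m1(k), m0(k), M1(k), M0(k), dm(k),
      w(k), d(k), t(k), u(k), A((size_t)k * k), L((size_t)k * k),
      sc(n);
    // full-data means and ridge-stabilized pooled scatter, factored
    // once per subset; each LOOCV fold is an exact rank-one downdate:
    // deleting sample i from class c gives
    //   Sw_fold = Sw_full - (n_c/(n_c-1)) (x_i - m_c)(x_i - m_c)^T,
    // solved via Sherman-Morrison on the prefactored matrix.
    for (int j = 0; j < k; ++j) {
      M1[j] = st.s1[j] / st.n1;
      M0[j] = st.s0[j] / st.n0;
    }
    for (int j = 0; j < k; ++j)
      for (int l = 0; l < k; ++l)
        L[j + l * k] = st.S[j + l * k] - st.n1 * M1[j] * M1[l]
          - st.n0 * M0[j] * M0[l];
    for (int j = 0; j < k; ++j) L[j + j * k] += ridge;
    if (!chol_factor(L, k))
      stop("singular within-class scatter; use a positive ridge");

    int correct = 0;
    for (int i = 0; i < n; ++i) {
      const int yi = y[i];
      const int n1f = st.n1 - yi, n0f = st.n0 - (1 - yi);
      const double gamma = yi ? (double)st.n1 / n1f
                              : (double)st.n0 / n0f;
      for (int j = 0; j < k; ++j) {
        xi[j] = st.Xs[i + (size_t)j * n];
        d[j] = xi[j] - (yi ? M1[j] : M0[j]);
        const double s1f = st.s1[j] - yi * xi[j];
        const double s0f = st.s0[j] - (1 - yi) * xi[j];
        m1[j] = s1f / n1f;
        m0[j] = s0f / n0f;
        dm[j] = m1[j] - m0[j];
      }
      chol_solve_factored(L, d.data(), t.data(), k);
      chol_solve_factored(L, dm.data(), u.data(), k);
      double dt = 0.0, du = 0.0;
      for (int j = 0; j < k; ++j) {
        dt += d[j] * t[j];
        du += d[j] * u[j];
      }
      const double denom = 1.0 - gamma * dt;  // > 0 while Sw_fold is PD
      if (denom <= 0.0)
        stop("singular within-class scatter in a LOOCV fold; "
             "use a positive ridge");
      const double coef = gamma * du / denom;
      double mid = 0.0, sco = 0.0;
      for (int j = 0; j < k; ++j) {
        w[j] = u[j] + coef * t[j];
        mid += w[j] * (m1[j] + m0[j]);
        sco += w[j] * xi[j];
      }
      double b = -0.5 * mid;
      if (empirical) b += std::log((double)n1f / n0f);
      const int pred = (sco + b > 0.0) ? 1 : 0;
      if (pred == yi) ++correct;
    }
    out(s, 0) = (double)correct / n;

    // training AUC of the full-data fit
    double b_full = 0.0;
    if (!fit_full(st, ridge, empirical, w, b_full, A, m1, m0, dm))
      stop("singular within-class scatter; use a positive ridge");
    for (int i = 0; i < n; ++i) {
      double v = b_full;
      for (int j = 0; j < k; ++j) v += w[j] * st.Xs[i + (size_t)j * n];
      sc[i] = v;
    }
    out(s, 1) = auc_from_scores(sc, y);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
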