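// Monte-Carlo cross-validation engine for the exhaustive low-order logistic
// model search. All randomness comes from a splitmix64 stream keyed by
// (master seed, variable set, subsample index), so results do not depend on
// model enumeration order or on how work is chunked.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Largest model is intercept + 3 variables.
#define MAXP 4

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {
    for (int i = 0; i < 3; ++i) splitmix64(s);
  }
  uint64_t next() { return splitmix64(s); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static void shuffle_idx(std::vector<int> &v, Rng &rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(v[i], v[j]);
  }
}

// hash a variable set (order-independent seed per model)
static uint64_t model_key(uint64_t seed, const int *vars, int p) {
  uint64_t h = seed ^ 0xA5A5A5A5DEADBEEFULL;
  uint64_t acc = 0;
  for (int j = 0; j < p; ++j) {
    uint64_t v = (uint64_t)(vars[j] + 1) * 0x9E3779B97F4A7C15ULL;
    splitmix64(v);
    acc ^= v;  // xor: symmetric in the variable set
  }
  h ^= acc;
  splitmix64(h);
  return h;
}

// Newton-Raphson ridge logistic regression; design is n x (p+1) row-major
// with leading intercept column. Penalty on slopes only.
static bool fit_logistic_small(const double *D, const double *y, int n, int p1,
                               double lambda, double *beta,
                               int max_iter = 60, double tol = 1e-8) {
  for (int j = 0; j < p1; ++j) beta[j] = 0.0;
  double H[MAXP][MAXP], g[MAXP], step[MAXP];
  for (int it = 0; it < max_iter; ++it) {
    for (int j = 0; j < p1; ++j) {
      g[j] = 0.0;
      for (int k = 0; k < p1; ++k) H[j][k] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      const double *xi = D + (size_t)i * p1;
      double eta = 0.0;
      for (int j = 0; j < p1; ++j) eta += xi[j] * beta[j];
      if (eta > 30.0) eta = 30.0;
      if (eta < -30.0) eta = -30.0;
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double r = y[i] - mu;
      for (int j = 0; j < p1; ++j) {
        g[j] += xi[j] * r;
        for (int k = j; k < p1; ++k) H[j][k] += w * xi[j] * xi[k];
      }
    }
    for (int j = 1; j < p1; ++j) {
      g[j] -= lambda * beta[j];
      H[j][j] += lambda;
    }
    for (int j = 0; j < p1; ++j) {
      H[j][j] += 1e-12;
      for (int k = 0; k < j; ++k) H[j][k] = H[k][j];
    }
    // solve H step = g by Gaussian elimination with partial pivoting
    double A[MAXP][MAXP + 1];
    for (int j = 0; j < p1; ++j) {
      for (int k = 0; k < p1; ++k) A[j][k] = H[j][k];
      A[j][p1] = g[j];
    }
    for (int c = 0; c < p1; ++c) {
      int piv = c;
      for (int r2 = c + 1; r2 < p1; ++r2)
        if (std::fabs(A[r2][c]) > std::fabs(A[piv][c])) piv = r2;
      if (std::fabs(A[piv][c]) < 1e-300) return false;
      if (piv != c)
        for (int k = c; k <= p1; ++k) std::swap(A[c][k], A[piv][k]);
      for (int r2 = c + 1; r2 < p1; ++r2) {
        double f = A[r2][c] / A[c][c];
        for (int k = c; k <= p1; ++k) A[r2][k] -= f * A[c][k];
      }
    }
    for (int c = p1 - 1; c >= 0; --c) {
      double s = A[c][p1];
      for (int k = c + 1; k < p1; ++k) s -= A[c][k] * step[k];
      step[c] = s / A[c][c];
    }
    double m = 0.0;
    for (int j = 0; j < p1; ++j) m = std::max(m, std::fabs(step[j]));
    if (m > 10.0) {
      double f = 10.0 / m;
      for (int j = 0; j < p1; ++j) step[j] *= f;
    }
    for (int j = 0; j < p1; ++j) beta[j] += step[j];
    if (m < tol) break;
  }
  return true;
}

static inline double mcc_from_counts(double tp, double tn, double fp, double fn) {
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0.0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(den);
}

// Pick the probability threshold maximising training MCC. Prediction rule is
// "positive if p >= threshold"; ties resolved toward the smaller threshold.
static double tune_threshold(const std::vector<double> &prob,
                             const std::vector<int> &lab) {
  int n = (int)prob.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return prob[a] < prob[b]; });
  int P = 0, N = 0;
  for (int i = 0; i < n; ++i) (lab[i] ? P : N)++;
  // start with threshold = smallest prob: everything predicted positive
  double tp = P, fp = N, tn = 0, fn = 0;
  double best_mcc = mcc_from_counts(tp, tn, fp, fn);
  double best_thr = prob[ord[0]];
  int i = 0;
  while (i < n) {
    double v = prob[ord[i]];
    // flip all samples with prob == v to predicted-negative
    while (i < n && prob[ord[i]] == v) {
      if (lab[ord[i]]) { tp -= 1; fn += 1; } else { fp -= 1; tn += 1; }
      ++i;
    }
    double thr = (i < n) ? prob[ord[i]] : (v + 1.0);  // above max: all negative
    double m = mcc_from_counts(tp, tn, fp, fn);
    if (m > best_mcc + 1e-12) { best_mcc = m; best_thr = thr; }
  }
  return best_thr;
}

// [[Rcpp::export]]
NumericVector cpp_fit_logistic(NumericMatrix X, IntegerVector y, double lambda) {
  int n = X.nrow(), p = X.ncol();
  if (p > MAXP - 1) stop("at most %d variables supported", MAXP - 1);
  std::vector<double> D((size_t)n * (p + 1)), yy(n);
  for (int i = 0; i < n; ++i) {
    D[(size_t)i * (p + 1)] = 1.0;
    for (int j = 0; j < p; ++j) D[(size_t)i * (p + 1) + j + 1] = X(i, j);
    yy[i] = y[i];
  }
  double beta[MAXP];
  if (!fit_logistic_small(D.data(), yy.data(), n, p + 1, lambda, beta))
    stop("logistic fit failed (singular system)");
  NumericVector out(p + 1);
  for (int j = 0; j <= p; ++j) out[j] = beta[j];
  return out;
}

// Evaluate a batch of candidate models by repeated stratified subsampling.
//
// X: n x k feature matrix (NA allowed); y: 0/1 labels; models: list of 1-based
// column index vectors (length 1..3). Per subsample: stratified 2/3-1/3 split
// among complete cases, standardisation by training statistics, ridge logistic
// fit, training-MCC threshold tuning, then test-set confusion counts.
// Returns one row per model:
//   mcc, mmce, ppv, npv, n_complete, n_subsamples_used, npv_defined, ppv_defined
// [[Rcpp::export]]
NumericMatrix cpp_evaluate_models(NumericMatrix X, IntegerVector y, List models,
                                  int n_subsamples, double train_frac,
                                  double lambda, double seed,
                                  bool standardize = true) {
  int n = X.nrow();
  int n_models = models.size();
  uint64_t master = (uint64_t)seed;
  NumericMatrix out(n_models, 8);
  colnames(out) = CharacterVector::create("mcc", "mmce", "ppv", "npv",
                                          "n_complete", "n_eval",
                                          "npv_defined", "ppv_defined");
  std::vector<int> pos, neg, tr, te;
  std::vector<double> Dtr, Dte, ytr, probs;
  std::vector<int> lab;

  for (int m = 0; m < n_models; ++m) {
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
    IntegerVector vars = models[m];
    int p = vars.size();
    if (p < 1 || p > MAXP - 1) stop("model %d: size must be 1..%d", m + 1, MAXP - 1);
    int vidx[MAXP];
    for (int j = 0; j < p; ++j) vidx[j] = vars[j] - 1;
    // complete cases for this variable set
    pos.clear(); neg.clear();
    for (int i = 0; i < n; ++i) {
      bool ok = true;
      for (int j = 0; j < p; ++j)
        if (!R_finite(X(i, vidx[j]))) { ok = false; break; }
      if (!ok) continue;
      if (y[i] == 1) pos.push_back(i); else neg.push_back(i);
    }
    int n_pos = (int)pos.size(), n_neg = (int)neg.size();
    out(m, 4) = n_pos + n_neg;
    if (n_pos < 2 || n_neg < 1) {
      out(m, 0) = NA_REAL; out(m, 1) = NA_REAL;
      out(m, 2) = NA_REAL; out(m, 3) = NA_REAL;
      continue;
    }
    int tr_pos = (int)std::lround(train_frac * n_pos);
    tr_pos = std::max(1, std::min(tr_pos, n_pos - 1));
    int tr_neg = (int)std::lround(train_frac * n_neg);
    tr_neg = std::max(1, std::min(tr_neg, std::max(1, n_neg - 1)));
    if (n_neg == 1) tr_neg = 1;  // lone negative goes to training

    uint64_t key = model_key(master, vidx, p);
    double sum_mcc = 0, sum_mmce = 0, sum_ppv = 0, sum_npv = 0;
    int n_eval = 0, ppv_def = 0, npv_def = 0;

    for (int s = 0; s < n_subsamples; ++s) {
      Rng rng(key + 0x9E3779B97F4A7C15ULL * (uint64_t)(s + 1));
      shuffle_idx(pos, rng);
      shuffle_idx(neg, rng);
      tr.clear(); te.clear();
      for (int i = 0; i < n_pos; ++i) (i < tr_pos ? tr : te).push_back(pos[i]);
      for (int i = 0; i < n_neg; ++i) (i < tr_neg ? tr : te).push_back(neg[i]);
      if (te.empty()) continue;
      int ntr = (int)tr.size(), nte = (int)te.size(), p1 = p + 1;
      // training statistics
      double mean[MAXP] = {0}, sd[MAXP] = {0};
      for (int j = 0; j < p; ++j) {
        double su = 0;
        for (int i = 0; i < ntr; ++i) su += X(tr[i], vidx[j]);
        mean[j] = su / ntr;
        double ss = 0;
        for (int i = 0; i < ntr; ++i) {
          double d = X(tr[i], vidx[j]) - mean[j];
          ss += d * d;
        }
        sd[j] = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 1.0;
        if (!standardize) { mean[j] = 0.0; sd[j] = 1.0; }
        if (sd[j] < 1e-12) sd[j] = 1.0;
      }
      Dtr.assign((size_t)ntr * p1, 1.0);
      ytr.resize(ntr);
      lab.resize(ntr);
      for (int i = 0; i < ntr; ++i) {
        for (int j = 0; j < p; ++j)
          Dtr[(size_t)i * p1 + j + 1] = (X(tr[i], vidx[j]) - mean[j]) / sd[j];
        ytr[i] = y[tr[i]];
        lab[i] = y[tr[i]];
      }
      double beta[MAXP];
      if (!fit_logistic_small(Dtr.data(), ytr.data(), ntr, p1, lambda, beta))
        continue;
      probs.resize(ntr);
      for (int i = 0; i < ntr; ++i) {
        double eta = beta[0];
        for (int j = 0; j < p; ++j) eta += beta[j + 1] * Dtr[(size_t)i * p1 + j + 1];
        probs[i] = 1.0 / (1.0 + std::exp(-eta));
      }
      double thr = tune_threshold(probs, lab);
      // test
      double tp = 0, tn = 0, fp = 0, fn = 0;
      for (int i = 0; i < nte; ++i) {
        double eta = beta[0];
        for (int j = 0; j < p; ++j)
          eta += beta[j + 1] * (X(te[i], vidx[j]) - mean[j]) / sd[j];
        double pr = 1.0 / (1.0 + std::exp(-eta));
        int pred = pr >= thr ? 1 : 0;
        if (pred == 1) { if (y[te[i]] == 1) tp++; else fp++; }
        else           { if (y[te[i]] == 1) fn++; else tn++; }
      }
      sum_mcc += mcc_from_counts(tp, tn, fp, fn);
      sum_mmce += (fp + fn) / (double)nte;
      if (tp + fp > 0) { sum_ppv += tp / (tp + fp); ppv_def++; }
      if (tn + fn > 0) { sum_npv += tn / (tn + fn); npv_def++; }
      n_eval++;
    }
    out(m, 0) = n_eval ? sum_mcc / n_eval : NA_REAL;
    out(m, 1) = n_eval ? sum_mmce / n_eval : NA_REAL;
    out(m, 2) = ppv_def ? sum_ppv / ppv_def : NA_REAL;
    out(m, 3) = npv_def ? sum_npv / npv_def : NA_REAL;
    out(m, 5) = n_eval;
    out(m, 6) = npv_def;
    out(m, 7) = ppv_def;
  }
  return out;
}
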