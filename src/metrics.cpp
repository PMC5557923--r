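#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted dispersion metrics on a species distance matrix.
// Communities are passed as 0-based index vectors of the species present
// plus their relative abundances (summing to 1 within each community).
// A permutation `perm` relabels species: the distance between species i and
// j under the shuffle is D(perm[i], perm[j]). The identity permutation gives
// the observed values.

static inline double dist_at(const NumericMatrix& D, const IntegerVector& perm,
                             int i, int j) {
  return D(perm[i], perm[j]);
}

// PW = sum_{i != j} w_i w_j d_ij / sum_{i != j} w_i w_j
static double pw_one(const IntegerVector& idx, const NumericVector& w,
                     const NumericMatrix& D, const IntegerVector& perm) {
  int k = idx.size();
  if (k < 2) return NA_REAL;
  double num = 0.0, den = 0.0;
  for (int a = 0; a < k - 1; ++a) {
    for (int b = a + 1; b < k; ++b) {
      double ww = w[a] * w[b];
      num += ww * dist_at(D, perm, idx[a], idx[b]);
      den += ww;
    }
  }
  return num / den;
}

// NN = sum_i w_i min_{j != i} d_ij
static double nn_one(const IntegerVector& idx, const NumericVector& w,
                     const NumericMatrix& D, const IntegerVector& perm) {
  int k = idx.size();
  if (k < 2) return NA_REAL;
  double out = 0.0;
  for (int a = 0; a < k; ++a) {
    double mn = R_PosInf;
    for (int b = 0; b < k; ++b) {
      if (b == a) continue;
      double d = dist_at(D, perm, idx[a], idx[b]);
      if (d < mn) mn = d;
    }
    out += w[a] * mn;
  }
  return out;
}

// Dpw = sum_{i in A, j in B} wA_i wB_j d_ij
static double dpw_one(const IntegerVector& ia, const NumericVector& wa,
                      const IntegerVector& ib, const NumericVector& wb,
                      const NumericMatrix& D, const IntegerVector& perm) {
  double out = 0.0;
  for (int a = 0; a < ia.size(); ++a)
    for (int b = 0; b < ib.size(); ++b)
      out += wa[a] * wb[b] * dist_at(D, perm, ia[a], ib[b]);
  return out;
}

// Dnn = 0.5 * (sum_{i in A} wA_i min_{j in B} d_ij +
//              sum_{j in B} wB_j min_{i in A} d_ij)
static double dnn_one(const IntegerVector& ia, const NumericVector& wa,
                      const IntegerVector& ib, const NumericVector& wb,
                      const NumericMatrix& D, const IntegerVector& perm) {
  double s1 = 0.0, s2 = 0.0;
  for (int a = 0; a < ia.size(); ++a) {
    double mn = R_PosInf;
    for (int b = 0; b < ib.size(); ++b) {
      double d = dist_at(D, perm, ia[a], ib[b]);
      if (d < mn) mn = d;
    }
    s1 += wa[a] * mn;
  }
  for (int b = 0; b < ib.size(); ++b) {
    double mn = R_PosInf;
    for (int a = 0; a < ia.size(); ++a) {
      double d = dist_at(D, perm, ia[a], ib[b]);
      if (d < mn) mn = d;
    }
    s2 += wb[b] * mn;
  }
  return 0.5 * (s1 + s2);
}

static IntegerVector identity_perm(int n) {
  IntegerVector p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  return p;
}

// Draw a uniform permutation of 0..n-1 with R's RNG (reproducible under
// set.seed on the R side).
static IntegerVector random_perm(int n) {
  IntegerVector p = Rcpp::sample(n, n, false) - 1;
  return p;
}

// [[Rcpp::export]]
NumericMatrix alpha_metrics_cpp(List idx, List w, NumericMatrix D) {
  int n = idx.size();
  IntegerVector perm = identity_perm(D.nrow());
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("PW", "NN");
  for (int c = 0; c < n; ++c) {
    IntegerVector ic = idx[c];
    NumericVector wc = w[c];
    out(c, 0) = pw_one(ic, wc, D, perm);
    out(c, 1) = nn_one(ic, wc, D, perm);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix beta_metrics_cpp(List idxA, List wA, List idxB, List wB,
                               NumericMatrix D) {
  int n = idxA.size();
  IntegerVector perm = identity_perm(D.nrow());
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("Dpw", "Dnn");
  for (int c = 0; c < n; ++c) {
    IntegerVector ia = idxA[c], ib = idxB[c];
    NumericVector wa = wA[c], wb = wB[c];
    out(c, 0) = dpw_one(ia, wa, ib, wb, D, perm);
    out(c, 1) = dnn_one(ia, wa, ib, wb, D, perm);
  }
  return out;
}

// Null moments for the alpha metrics: one pool-wide taxa shuffle is shared
// by every community within an iteration, preserving cross-community
// structure. Returns mean and SD (n-1 denominator) over n_iter shuffles.
// [[Rcpp::export]]
List null_alpha_cpp(List idx, List w, NumericMatrix D, int n_iter) {
  int n = idx.size(), npool = D.nrow();
  NumericMatrix s(n, 2), s2(n, 2);
  for (int it = 0; it < n_iter; ++it) {
    IntegerVector perm = random_perm(npool);
    for (int c = 0; c < n; ++c) {
      IntegerVector ic = idx[c];
      NumericVector wc = w[c];
      double pw = pw_one(ic, wc, D, perm);
      double nn = nn_one(ic, wc, D, perm);
      if (!ISNA(pw)) { s(c, 0) += pw; s2(c, 0) += pw * pw; }
      if (!ISNA(nn)) { s(c, 1) += nn; s2(c, 1) += nn * nn; }
    }
  }
  NumericMatrix mean(n, 2), sd(n, 2);
  colnames(mean) = CharacterVector::create("PW", "NN");
  colnames(sd) = CharacterVector::create("PW", "NN");
  for (int c = 0; c < n; ++c) {
    IntegerVector ic = idx[c];
    for (int m = 0; m < 2; ++m) {
      if (ic.size() < 2) { mean(c, m) = NA_REAL; sd(c, m) = NA_REAL; continue; }
      double mu = s(c, m) / n_iter;
      double var = n_iter > 1 ? (s2(c, m) - n_iter * mu * mu) / (n_iter - 1) : NA_REAL;
      if (var < 0) var = 0; // numeric guard
      mean(c, m) = mu;
      sd(c, m) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// [[Rcpp::export]]
List null_beta_cpp(List idxA, List wA, List idxB, List wB, NumericMatrix D,
                   int n_iter) {
  int n = idxA.size(), npool = D.nrow();
  NumericMatrix s(n, 2), s2(n, 2);
  for (int it = 0; it < n_iter; ++it) {
    IntegerVector perm = random_perm(npool);
    for (int c = 0; c < n; ++c) {
      IntegerVector ia = idxA[c], ib = idxB[c];
      NumericVector wa = wA[c], wb = wB[c];
      double dpw = dpw_one(ia, wa, ib, wb, D, perm);
      double dnn = dnn_one(ia, wa, ib, wb, D, perm);
      s(c, 0) += dpw; s2(c, 0) += dpw * dpw;
      s(c, 1) += dnn; s2(c, 1) += dnn * dnn;
    }
  }
  NumericMatrix mean(n, 2), sd(n, 2);
  colnames(mean) = CharacterVector::create("Dpw", "Dnn");
  colnames(sd) = CharacterVector::create("Dpw", "Dnn");
  for (int c = 0; c < n; ++c) {
    for (int m = 0; m < 2; ++m) {
      double mu = s(c, m) / n_iter;
      double var = n_iter > 1 ? (s2(c, m) - n_iter * mu * mu) / (n_iter - 1) : NA_REAL;
      if (var < 0) var = 0;
      mean(c, m) = mu;
      sd(c, m) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
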