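// Hot path of parameter training: evaluate the model's continuous output
// utility for every record of a dataset, given precomputed per-attribute
// matching matrices. Mirrors the reference R implementation
// (brb_infer_matrix); the two are cross-checked in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

// match: list of M matrices, each T x J_i, matching degrees per record and
//        referential value (independent of the trainable parameters)
// ante:  L x M antecedent index matrix (1-based)
// theta: L rule weights; dbar: M normalised attribute weights
// B:     L x N consequent belief matrix; u: N grade utilities
// [[Rcpp::export]]
NumericVector cpp_brb_utilities(List match, IntegerMatrix ante,
                                NumericVector theta, NumericVector dbar,
                                NumericMatrix B, NumericVector u) {
  const int M = ante.ncol(), L = ante.nrow(), N = B.ncol();
  const int T = as<NumericMatrix>(match[0]).nrow();

  // per-attribute matching degrees raised to the normalised attribute
  // weights (skipped when the exponent is exactly 1)
  std::vector<std::vector<double>> pw(M);
  std::vector<const double*> pwp(M);
  std::vector<int> nref(M);
  for (int i = 0; i < M; ++i) {
    NumericMatrix mi = match[i];
    if (mi.nrow() != T) stop("matching matrices disagree on record count");
    nref[i] = mi.ncol();
    if (dbar[i] == 1.0) {
      pwp[i] = REAL(mi);
    } else {
      pw[i].resize((size_t) T * nref[i]);
      const double *src = REAL(mi);
      for (size_t p = 0; p < pw[i].size(); ++p)
        pw[i][p] = std::pow(src[p], dbar[i]);
      pwp[i] = pw[i].data();
    }
  }

  std::vector<double> s(L);
  for (int k = 0; k < L; ++k) {
    double t = 0;
    for (int j = 0; j < N; ++j) t += B(k, j);
    s[k] = t;
  }

  // activation numerators, column-wise over rules
  std::vector<double> act((size_t) T * L);
  std::vector<double> tot(T, 0.0);
  for (int k = 0; k < L; ++k) {
    double *ak = &act[(size_t) T * k];
    const double *c0 = pwp[0] + (size_t) T * (ante(k, 0) - 1);
    const double th = theta[k];
    for (int r = 0; r < T; ++r) ak[r] = th * c0[r];
    for (int i = 1; i < M; ++i) {
      const double *ci = pwp[i] + (size_t) T * (ante(k, i) - 1);
      for (int r = 0; r < T; ++r) ak[r] *= ci[r];
    }
    for (int r = 0; r < T; ++r) tot[r] += ak[r];
  }
  for (int r = 0; r < T; ++r) {
    if (!(tot[r] > 0)) stop("no rule activated for record %d", r + 1);
    tot[r] = 1.0 / tot[r];
  }
  for (int k = 0; k < L; ++k) {
    double *ak = &act[(size_t) T * k];
    for (int r = 0; r < T; ++r) ak[r] *= tot[r];  // now activation weights
  }

  // analytic evidential-reasoning aggregation
  std::vector<double> t1((size_t) T * N, 1.0), t2(T, 1.0), t3(T, 1.0);
  for (int k = 0; k < L; ++k) {
    const double *wk = &act[(size_t) T * k];
    const double sk = s[k];
    for (int j = 0; j < N; ++j) {
      double *t1j = &t1[(size_t) T * j];
      const double bkj = B(k, j);
      for (int r = 0; r < T; ++r)
        t1j[r] *= wk[r] * bkj + 1 - wk[r] * sk;
    }
    for (int r = 0; r < T; ++r) {
      t2[r] *= 1 - wk[r] * sk;
      t3[r] *= 1 - wk[r];
    }
  }

  NumericVector res(T);
  for (int r = 0; r < T; ++r) {
    double sum1 = 0;
    for (int j = 0; j < N; ++j) sum1 += t1[(size_t) T * j + r];
    const double denom = sum1 - (N - 1) * t2[r] - t3[r];
    if (!(denom > 1e-12))
      stop("degenerate evidential-reasoning combination (zero denominator)");
    double y = 0;
    for (int j = 0; j < N; ++j) {
      double bj = (t1[(size_t) T * j + r] - t2[r]) / denom;
      if (bj < 0) bj = 0; else if (bj > 1) bj = 1;
      y += u[j] * bj;
    }
    res[r] = y;
  }
  return res;
}
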