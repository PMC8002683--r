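#include <Rcpp.h>
using namespace Rcpp;

// Maximum Caliber one-step transition matrices and conditional path moments.
//
// Per-frame micro-trajectories out of a state with N proteins are labelled by
// (l_alpha, l_A): l_alpha in 0..M new productions, l_A in 0..N survivors.
// Their probability is
//   P(l_alpha, l_A | N) = Q^-1 C(N, l_A) exp(h_a*l_alpha + h_A*l_A + K_A*l_alpha*l_A)
// and the next state is j = l_alpha + l_A.  All sums use a max-shift
// (log-sum-exp) for numerical safety.
//
// State spaces follow the package convention: tracked counts 0..nmax-1 plus
// one absorbing sink (index nmax, zero-based) collecting any j >= nmax.

// log factorials 0..n
static std::vector<double> lfact_table(int n) {
  std::vector<double> lf(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) lf[k] = lf[k - 1] + std::log((double) k);
  return lf;
}

// [[Rcpp::export]]
NumericMatrix maxcal_transition_sgaa_cpp(double h_a, double h_A, double K_A,
                                         int M, int nmax) {
  int dim = nmax + 1;
  NumericMatrix P(dim, dim);
  std::vector<double> lf = lfact_table(nmax);
  std::vector<double> sj(nmax + M + 1);
  std::vector<double> lw((M + 1) * (nmax + 1));
  for (int i = 0; i < nmax; ++i) {
    double mx = R_NegInf;
    int idx = 0;
    for (int la = 0; la <= M; ++la)
      for (int lA = 0; lA <= i; ++lA, ++idx) {
        double v = lf[i] - lf[lA] - lf[i - lA] +
          h_a * la + h_A * lA + K_A * (double) la * lA;
        lw[idx] = v;
        if (v > mx) mx = v;
      }
    std::fill(sj.begin(), sj.begin() + (i + M + 1), 0.0);
    double Q = 0.0;
    idx = 0;
    for (int la = 0; la <= M; ++la)
      for (int lA = 0; lA <= i; ++lA, ++idx) {
        double w = std::exp(lw[idx] - mx);
        sj[la + lA] += w;
        Q += w;
      }
    double sink = 0.0;
    for (int j = 0; j <= i + M; ++j) {
      double p = sj[j] / Q;
      if (j < nmax) P(j, i) = p; else sink += p;
    }
    P(nmax, i) = sink;
  }
  P(nmax, nmax) = 1.0;  // absorbing sink
  return P;
}

// Conditional means <l_alpha>_N and <l_A>_N for N = 0..nmax-1.
// [[Rcpp::export]]
NumericMatrix maxcal_means_sgaa_cpp(double h_a, double h_A, double K_A,
                                    int M, int nmax) {
  NumericMatrix out(2, nmax);
  std::vector<double> lf = lfact_table(nmax);
  std::vector<double> lw((M + 1) * (nmax + 1));
  for (int i = 0; i < nmax; ++i) {
    double mx = R_NegInf;
    int idx = 0;
    for (int la = 0; la <= M; ++la)
      for (int lA = 0; lA <= i; ++lA, ++idx) {
        double v = lf[i] - lf[lA] - lf[i - lA] +
          h_a * la + h_A * lA + K_A * (double) la * lA;
        lw[idx] = v;
        if (v > mx) mx = v;
      }
    double Q = 0.0, sa = 0.0, sA = 0.0;
    idx = 0;
    for (int la = 0; la <= M; ++la)
      for (int lA = 0; lA <= i; ++lA, ++idx) {
        double w = std::exp(lw[idx] - mx);
        Q += w; sa += la * w; sA += lA * w;
      }
    out(0, i) = sa / Q;
    out(1, i) = sA / Q;
  }
  return out;
}

static inline double ts_logw(const std::vector<double>& lf,
                             int i, int k, int la, int lA, int lb, int lB,
                             double h_a, double h_A, double K_Aa, double K_Ab) {
  return lf[i] - lf[lA] - lf[i - lA] + lf[k] - lf[lB] - lf[k - lB] +
    h_a * (la + lb) + h_A * (lA + lB) +
    K_Aa * ((double) la * lA + (double) lb * lB) +
    K_Ab * ((double) lb * lA + (double) la * lB);
}

// Toggle-switch one-step transition matrix over joint states (N_A, N_B),
// linear index i + nmax*k (zero-based), sink appended last.  Intended for
// moderate nmax; the cost grows as (M+1)^2 * (nmax^2/2)^2.
// [[Rcpp::export]]
NumericMatrix maxcal_transition_ts_cpp(double h_a, double h_A,
                                       double K_Aa, double K_Ab,
                                       int M, int nmax) {
  int dim = nmax * nmax + 1;
  NumericMatrix P(dim, dim);
  std::vector<double> lf = lfact_table(nmax);
  for (int k = 0; k < nmax; ++k)
    for (int i = 0; i < nmax; ++i) {
      int col = i + nmax * k;
      double mx = R_NegInf;
      for (int la = 0; la <= M; ++la)
        for (int lA = 0; lA <= i; ++lA)
          for (int lb = 0; lb <= M; ++lb)
            for (int lB = 0; lB <= k; ++lB) {
              double lw = ts_logw(lf, i, k, la, lA, lb, lB, h_a, h_A, K_Aa, K_Ab);
              if (lw > mx) mx = lw;
            }
      double Q = 0.0, sink = 0.0;
      // accumulate unnormalised masses by target (j, l)
      NumericMatrix tgt(i + M + 1, k + M + 1);
      for (int la = 0; la <= M; ++la)
        for (int lA = 0; lA <= i; ++lA)
          for (int lb = 0; lb <= M; ++lb)
            for (int lB = 0; lB <= k; ++lB) {
              double w = std::exp(ts_logw(lf, i, k, la, lA, lb, lB,
                                          h_a, h_A, K_Aa, K_Ab) - mx);
              tgt(la + lA, lb + lB) += w;
              Q += w;
            }
      for (int j = 0; j <= i + M; ++j)
        for (int l = 0; l <= k + M; ++l) {
          double p = tgt(j, l) / Q;
          if (p == 0.0) continue;
          if (j < nmax && l < nmax) P(j + nmax * l, col) = p;
          else sink += p;
        }
      P(dim - 1, col) = sink;
    }
  P(dim - 1, dim - 1) = 1.0;
  return P;
}

// Conditional means (<l_alpha>, <l_A>, <l_beta>, <l_B>) per joint state.
// [[Rcpp::export]]
NumericMatrix maxcal_means_ts_cpp(double h_a, double h_A,
                                  double K_Aa, double K_Ab,
                                  int M, int nmax) {
  NumericMatrix out(4, nmax * nmax);
  std::vector<double> lf = lfact_table(nmax);
  for (int k = 0; k < nmax; ++k)
    for (int i = 0; i < nmax; ++i) {
      int col = i + nmax * k;
      double mx = R_NegInf;
      for (int la = 0; la <= M; ++la)
        for (int lA = 0; lA <= i; ++lA)
          for (int lb = 0; lb <= M; ++lb)
            for (int lB = 0; lB <= k; ++lB) {
              double lw = ts_logw(lf, i, k, la, lA, lb, lB, h_a, h_A, K_Aa, K_Ab);
              if (lw > mx) mx = lw;
            }
      double Q = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0, s4 = 0.0;
      for (int la = 0; la <= M; ++la)
        for (int lA = 0; lA <= i; ++lA)
          for (int lb = 0; lb <= M; ++lb)
            for (int lB = 0; lB <= k; ++lB) {
              double w = std::exp(ts_logw(lf, i, k, la, lA, lb, lB,
                                          h_a, h_A, K_Aa, K_Ab) - mx);
              Q += w; s1 += la * w; s2 += lA * w; s3 += lb * w; s4 += lB * w;
            }
      out(0, col) = s1 / Q;
      out(1, col) = s2 / Q;
      out(2, col) = s3 / Q;
      out(3, col) = s4 / Q;
    }
  return out;
}
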