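#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) for a small reaction
// network with mass-action or Hill-type propensities, recording selected
// species at uniform frame times.
//
// Propensity encodings (rtype):
//   0  mass action: rate * prod_s [ x_s (x_s-1) ... (x_s-nu+1) / nu! ] * comb_mult
//   1  Hill activation: hpar = (mod_idx, g_base, g_amp, K, n)
//        a = g_base + g_amp * x^n / (x^n + K)
//   2  Hill repression: hpar = (mod_idx, g_base, g_amp, K, n)
//        a = g_base + g_amp / (x^n + K)
//
// Uses R's RNG (unif_rand / exp_rand) so results are reproducible under
// set.seed() on the R side.

static inline double mass_action_prop(const IntegerVector& x,
                                      const IntegerMatrix& nu_in,
                                      int r, double rate, double comb_mult) {
  double a = rate * comb_mult;
  int nspec = nu_in.nrow();
  for (int s = 0; s < nspec; ++s) {
    int nu = nu_in(s, r);
    if (nu == 0) continue;
    int xs = x[s];
    if (xs < nu) return 0.0;
    if (nu == 1) {
      a *= (double) xs;
    } else if (nu == 2) {
      a *= (double) xs * (xs - 1) / 2.0;
    } else {
      double f = 1.0;
      for (int k = 0; k < nu; ++k) f *= (double)(xs - k) / (double)(k + 1);
      a *= f;
    }
  }
  return a;
}

static inline double hill_prop(const IntegerVector& x, const NumericMatrix& hpar,
                               int r, int rtype) {
  int mod = (int) hpar(0, r);
  double gb = hpar(1, r), ga = hpar(2, r), K = hpar(3, r), n = hpar(4, r);
  double xn = std::pow((double) x[mod], n);
  if (rtype == 1) {
    double denom = xn + K;
    return gb + (denom > 0.0 ? ga * xn / denom : 0.0);
  }
  return gb + ga / (xn + K);
}

// [[Rcpp::export]]
IntegerMatrix ssa_simulate_cpp(IntegerVector x0,
                               IntegerMatrix nu_in,
                               IntegerMatrix nu_delta,
                               NumericVector rate,
                               IntegerVector rtype,
                               NumericVector comb_mult,
                               NumericMatrix hpar,
                               double t_end,
                               double delta_t,
                               double burn_in,
                               IntegerVector record_idx) {
  int nreact = rate.size();
  int nrec = record_idx.size();
  int nframes = (int) std::floor((t_end - burn_in) / delta_t + 1e-9) + 1;
  IntegerMatrix out(nframes, nrec);
  IntegerVector x = clone(x0);
  NumericVector a(nreact);

  double t = 0.0;
  int frame = 0;

  while (frame < nframes) {
    double a0 = 0.0;
    for (int r = 0; r < nreact; ++r) {
      double ar;
      if (rtype[r] == 0) ar = mass_action_prop(x, nu_in, r, rate[r], comb_mult[r]);
      else ar = hill_prop(x, hpar, r, rtype[r]);
      if (ar < 0.0 || !R_finite(ar)) stop("non-finite or negative propensity");
      a[r] = ar;
      a0 += ar;
    }
    double t_next;
    if (a0 <= 0.0) {
      t_next = R_PosInf;  // absorbing: state stays constant
    } else {
      t_next = t + exp_rand() / a0;
    }
    // record all frames passed before the next event fires
    while (frame < nframes && burn_in + frame * delta_t <= t_next) {
      for (int s = 0; s < nrec; ++s) out(frame, s) = x[record_idx[s]];
      ++frame;
    }
    if (frame >= nframes) break;
    if (!R_finite(t_next)) break;  // no reactions possible, all frames done above
    // choose reaction
    double u = unif_rand() * a0;
    double cum = 0.0;
    int chosen = nreact - 1;
    for (int r = 0; r < nreact; ++r) {
      cum += a[r];
      if (u <= cum) { chosen = r; break; }
    }
    int nspec = x.size();
    for (int s = 0; s < nspec; ++s) {
      x[s] += nu_delta(s, chosen);
      if (x[s] < 0) stop("species count went negative (bad stoichiometry)");
    }
    t = t_next;
  }
  return out;
}

// Sample a discrete-time Markov chain given a column-stochastic transition
// matrix (columns indexed by the current state); used to simulate the
// Maximum Caliber chain for self-consistency checks.
// [[Rcpp::export]]
IntegerVector dtmc_sample_cpp(NumericMatrix P, int start, int nsteps) {
  int n = P.nrow();
  IntegerVector out(nsteps + 1);
  int s = start;  // zero-based
  out[0] = s;
  for (int k = 1; k <= nsteps; ++k) {
    double u = unif_rand();
    double cum = 0.0;
    int nxt = n - 1;
    for (int j = 0; j < n; ++j) {
      cum += P(j, s);
      if (u <= cum) { nxt = j; break; }
    }
    s = nxt;
    out[k] = s;
  }
  return out;
}
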