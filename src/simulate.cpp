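#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo encode-decode engine.
//
// Works in "internal" stimulus units: doubled-angle radians on [0, 2*pi) for
// circular spaces, raw stimulus values (e.g. % intensity) for bounded spaces.
// The R wrappers convert to and from user-facing units.
//
// Key identities exploited (both follow from divisive normalization, which
// fixes the summed expected count at gamma/N for every stimulus value):
//   * the total spike count K is Poisson(gamma/N) regardless of the stimulus,
//     and conditional on K the spiking neurons are i.i.d. draws from the
//     normalized tuning kernel at the target (Poisson superposition);
//   * the log likelihood of a pattern over candidate values theta reduces,
//     up to theta-independent constants, to a function of sufficient
//     statistics of the spiked preferred values: the resultant vector
//     (circular von Mises kernel) or the sum (bounded Gaussian kernel),
//     minus K * log S(theta) with S(theta) the summed unnormalized kernel.
// This makes one simulated response O(K + L) instead of O(M * L).
//
// Neuron identities are drawn with Walker's alias method (O(1) per spike,
// exactly two uniforms, so parallel runs that differ only in the tuning
// width consume identical RNG streams - common random numbers).

static inline double log_kernel(int circ, double x, double c, double inv2w2) {
  if (circ) {
    // exp((cos(x - c) - 1) / omega^2); inv2w2 here carries 1/omega^2
    return (std::cos(x - c) - 1.0) * inv2w2;
  }
  double d = x - c;
  return -d * d * inv2w2; // inv2w2 carries 1/(2 omega^2)
}

static void build_alias(const std::vector<double>& p, // normalized probs
                        std::vector<double>& prob, std::vector<int>& alias) {
  const int n = (int)p.size();
  prob.assign(n, 0.0); alias.assign(n, 0);
  std::vector<int> small, large;
  std::vector<double> q(n);
  for (int i = 0; i < n; ++i) {
    q[i] = p[i] * n;
    (q[i] < 1.0 ? small : large).push_back(i);
  }
  while (!small.empty() && !large.empty()) {
    int s = small.back(); small.pop_back();
    int l = large.back(); large.pop_back();
    prob[s] = q[s]; alias[s] = l;
    q[l] = (q[l] + q[s]) - 1.0;
    (q[l] < 1.0 ? small : large).push_back(l);
  }
  while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
  while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
}

// [[Rcpp::export]]
NumericVector pc_simulate_cpp(int space_type,
                              NumericVector targets,
                              NumericVector gain_eff,
                              IntegerVector fixed_k,
                              double omega,
                              NumericVector prefs,
                              NumericVector grid,
                              int decoder,
                              NumericVector log_prior,
                              int n_per_target) {
  const int circ = (space_type == 0);
  const int M = prefs.size();
  const int L = grid.size();
  const int T = targets.size();
  if (L < 1) stop("empty decoding grid");
  if (M < 2) stop("need at least 2 neurons");
  if (omega <= 0) stop("tuning width must be positive");
  if (decoder == 1 && log_prior.size() != L)
    stop("log_prior must match the decoding grid");

  const double inv2w2 = circ ? 1.0 / (omega * omega)
                             : 1.0 / (2.0 * omega * omega);

  // log S(theta_l) = log sum_j g_j(theta_l), and trig tables
  std::vector<double> logS(L), cosg, sing, grid2;
  std::vector<double> cospref, sinpref;
  if (circ) {
    cosg.resize(L); sing.resize(L);
    cospref.resize(M); sinpref.resize(M);
    for (int j = 0; j < M; ++j) {
      cospref[j] = std::cos(prefs[j]);
      sinpref[j] = std::sin(prefs[j]);
    }
  } else {
    grid2.resize(L);
    for (int l = 0; l < L; ++l) grid2[l] = grid[l] * grid[l];
  }
  {
    std::vector<double> lg(M);
    for (int l = 0; l < L; ++l) {
      double mx = R_NegInf;
      for (int j = 0; j < M; ++j) {
        lg[j] = log_kernel(circ, grid[l], prefs[j], inv2w2);
        if (lg[j] > mx) mx = lg[j];
      }
      double s = 0.0;
      for (int j = 0; j < M; ++j) s += std::exp(lg[j] - mx);
      logS[l] = mx + std::log(s);
      if (circ) { cosg[l] = std::cos(grid[l]); sing[l] = std::sin(grid[l]); }
    }
  }

  // With evenly spaced circular preferred values S(theta) is constant to
  // machine precision, so ML decoding reduces to snapping the resultant
  // angle to the nearest grid point (no scan over L needed).
  bool ml_shortcut = false;
  double grid0 = grid[0], gstep = 1.0;
  if (circ && decoder == 0 && L >= 2) {
    double mn = logS[0], mx = logS[0];
    for (int l = 1; l < L; ++l) {
      if (logS[l] < mn) mn = logS[l];
      if (logS[l] > mx) mx = logS[l];
    }
    gstep = grid[1] - grid[0];
    bool uniform = true;
    for (int l = 1; l < L; ++l)
      if (std::fabs(grid[l] - grid0 - l * gstep) > 1e-9) { uniform = false; break; }
    ml_shortcut = uniform && (mx - mn) < 1e-9;
  }

  NumericVector out((R_xlen_t)T * n_per_target);
  std::vector<double> atab, lg(M), p(M), score(L), w(L);
  std::vector<int> aidx;
  bool have_tables = false;
  double prev_target = 0.0;

  for (int t = 0; t < T; ++t) {
    // normalized tuning kernel at the target -> alias sampling tables;
    // reused when consecutive entries share a target value
    if (!have_tables || targets[t] != prev_target) {
      double mx = R_NegInf;
      for (int j = 0; j < M; ++j) {
        lg[j] = log_kernel(circ, targets[t], prefs[j], inv2w2);
        if (lg[j] > mx) mx = lg[j];
      }
      double acc = 0.0;
      for (int j = 0; j < M; ++j) { p[j] = std::exp(lg[j] - mx); acc += p[j]; }
      for (int j = 0; j < M; ++j) p[j] /= acc;
      build_alias(p, atab, aidx);
      have_tables = true;
      prev_target = targets[t];
    }

    for (int s = 0; s < n_per_target; ++s) {
      int K = fixed_k[t] >= 0 ? fixed_k[t]
                              : (int)R::rpois(gain_eff[t]);
      double Sx = 0.0, Sy = 0.0, S1 = 0.0;
      for (int k = 0; k < K; ++k) {
        int j = (int)(unif_rand() * M);
        if (j >= M) j = M - 1;
        if (unif_rand() >= atab[j]) j = aidx[j];
        if (circ) { Sx += cospref[j]; Sy += sinpref[j]; }
        else      { S1 += prefs[j]; }
      }

      int best = 0;
      if (decoder == 0 && ml_shortcut) {
        if (K > 0 && (Sx != 0.0 || Sy != 0.0)) {
          double phi = std::atan2(Sy, Sx);
          if (phi < 0) phi += 2.0 * M_PI;
          long idx = (long)std::floor((phi - grid0) / gstep + 0.5);
          idx %= L; if (idx < 0) idx += L;
          best = (int)idx;
        }
        out[(R_xlen_t)t * n_per_target + s] = grid[best];
        continue;
      }

      if (circ) {
        for (int l = 0; l < L; ++l)
          score[l] = (Sx * cosg[l] + Sy * sing[l]) * inv2w2 - K * logS[l];
      } else {
        for (int l = 0; l < L; ++l)
          score[l] = inv2w2 * (2.0 * grid[l] * S1 - K * grid2[l]) - K * logS[l];
      }

      if (decoder == 0) { // maximum likelihood; first max wins ties
        double bs = score[0];
        for (int l = 1; l < L; ++l)
          if (score[l] > bs) { bs = score[l]; best = l; }
      } else {            // one draw from the normalized posterior
        double m2 = R_NegInf;
        for (int l = 0; l < L; ++l) {
          w[l] = score[l] + log_prior[l];
          if (w[l] > m2) m2 = w[l];
        }
        if (!R_FINITE(m2)) stop("posterior has no mass on the grid");
        double tot2 = 0.0;
        // mass below exp(-40) of the mode cannot affect the draw
        for (int l = 0; l < L; ++l) {
          w[l] = (w[l] - m2 > -40.0) ? std::exp(w[l] - m2) : 0.0;
          tot2 += w[l];
        }
        double u = unif_rand() * tot2, run = 0.0;
        best = L - 1;
        for (int l = 0; l < L; ++l) {
          run += w[l];
          if (u <= run) { best = l; break; }
        }
      }
      out[(R_xlen_t)t * n_per_target + s] = grid[best];
    }
  }
  return out;
}
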