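#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample-entropy template-pair counts (Richman & Moorman convention:
// both template sets range over the first n - m points; self-matches
// excluded). Returns c(B, A): matches at length m and m + 1.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;            // number of templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}

// Sliding-window circular correlation for all unordered channel pairs.
// phi: n_ch x n_t wrapped phases. Window reference is the arithmetic
// sample mean of the wrapped phase (or the circular mean if circular_mean).
// Pairs are ordered (1,2),(1,3),...,(1,n),(2,3),... matching connection_map().
// Degenerate windows (zero deviation energy) give NA.
// [[Rcpp::export]]
NumericMatrix sliding_ccorr_cpp(NumericMatrix phi, int L, int step,
                                bool circular_mean) {
  const int n_ch = phi.nrow(), n_t = phi.ncol();
  const int n_win = (n_t - L) / step + 1;
  const int n_con = n_ch * (n_ch - 1) / 2;
  NumericMatrix out(n_con, n_win);
  std::vector<double> sdev(n_ch * L);
  std::vector<double> norm2(n_ch);
  for (int w = 0; w < n_win; ++w) {
    const int s0 = w * step;
    for (int c = 0; c < n_ch; ++c) {
      double ref;
      if (circular_mean) {
        double ss = 0.0, cc = 0.0;
        for (int t = 0; t < L; ++t) {
          ss += std::sin(phi(c, s0 + t));
          cc += std::cos(phi(c, s0 + t));
        }
        ref = std::atan2(ss, cc);
      } else {
        double acc = 0.0;
        for (int t = 0; t < L; ++t) acc += phi(c, s0 + t);
        ref = acc / L;
      }
      double n2 = 0.0;
      for (int t = 0; t < L; ++t) {
        const double s = std::sin(phi(c, s0 + t) - ref);
        sdev[c * L + t] = s;
        n2 += s * s;
      }
      norm2[c] = n2;
    }
    int k = 0;
    for (int i = 0; i < n_ch - 1; ++i) {
      for (int j = i + 1; j < n_ch; ++j, ++k) {
        const double den2 = norm2[i] * norm2[j];
        if (den2 <= 0.0) { out(k, w) = NA_REAL; continue; }
        double num = 0.0;
        const double *si = &sdev[i * L], *sj = &sdev[j * L];
        for (int t = 0; t < L; ++t) num += si[t] * sj[t];
        out(k, w) = num / std::sqrt(den2);
      }
    }
  }
  return out;
}

// Euler(-Maruyama) integration of the coupled phase-oscillator network
//   dtheta_i/dt = omega * (1 - a*cos(theta_i)
//                          + (1 - cos(theta_i)) * (K/N) * sum_j w_ij cos(theta_j)
//                          + Q * eta_i)
// em_noise: true  -> increment omega * Q * sqrt(dt) * N(0,1)  (SDE reading)
//           false -> increment dt * omega * Q * N(0,1)        (literal reading)
// Returns (n_steps + 1) columns including the initial state; unwrapped.
// [[Rcpp::export]]
NumericMatrix euler_phase_sim_cpp(NumericVector theta0, double omega, double a,
                                  double K, NumericMatrix W, double Q,
                                  double dt, int n_steps, bool em_noise) {
  const int N = theta0.size();
  NumericMatrix out(N, n_steps + 1);
  std::vector<double> th(N), cth(N);
  for (int i = 0; i < N; ++i) { th[i] = theta0[i]; out(i, 0) = th[i]; }
  const double sqdt = std::sqrt(dt);
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < N; ++i) cth[i] = std::cos(th[i]);
    NumericVector eta = (Q > 0.0) ? rnorm(N) : NumericVector(N);
    for (int i = 0; i < N; ++i) {
      double coup = 0.0;
      for (int j = 0; j < N; ++j) if (j != i) coup += W(i, j) * cth[j];
      double drift = omega * (1.0 - a * cth[i] + (1.0 - cth[i]) * (K / N) * coup);
      double incr = drift * dt;
      if (Q > 0.0)
        incr += em_noise ? omega * Q * sqdt * eta[i] : dt * omega * Q * eta[i];
      th[i] += incr;
      if (!std::isfinite(th[i]))
        stop("integration diverged (non-finite phase) at step %d", s);
      out(i, s) = th[i];
    }
  }
  return out;
}
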