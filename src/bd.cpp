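// Step-by-step random-flight (Brownian dynamics) reference simulator for
// tiny systems; the independent validation oracle for the IRT engine.
// Displacements are Gaussian with variance 2*D*dt per axis. Absorbing
// encounters are detected on end-of-step positions plus the standard
// bridging probability exp(-(r1-R)(r2-R)/(D*dt)) of having crossed the
// encounter sphere inside the step, which removes the O(sqrt(dt))
// first-passage bias of bare end-of-step detection; the caller still
// enforces sqrt(2*Dmax*dt) < R/5. Partially controlled channels react
// inside the encounter radius with probability 1 - exp(-q*dt) per step
// (volume-reactivity model; q tuned by the caller to the target rate).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".bd_pair_cpp")]]
IntegerVector bd_pair_cpp(double r0, double R, double D, double dt,
                          NumericVector grid_times, int n_rep, double q) {
  // simulates the relative coordinate with mutual diffusion D;
  // returns the number of replicates that have reacted by each grid time
  int ng = grid_times.size();
  IntegerVector reacted(ng);
  double sd = std::sqrt(2.0 * D * dt);
  double t_end = grid_times[ng - 1];
  bool absorbing = !R_finite(q);
  double pstep = absorbing ? 1.0 : -std::expm1(-q * dt);
  for (int rep = 0; rep < n_rep; ++rep) {
    double x = r0, y = 0.0, z = 0.0, t = 0.0;
    double t_react = R_PosInf;
    double r_prev = r0;
    while (t < t_end) {
      x += norm_rand() * sd; y += norm_rand() * sd; z += norm_rand() * sd;
      t += dt;
      double r = std::sqrt(x * x + y * y + z * z);
      if (r < R) {
        if (absorbing || unif_rand() < pstep) { t_react = t; break; }
      } else if (absorbing && R > 0.0) {
        // crossed-and-returned within the step
        double pbridge = std::exp(-(r_prev - R) * (r - R) / (D * dt));
        if (unif_rand() < pbridge) { t_react = t; break; }
      }
      r_prev = r;
    }
    for (int g = 0; g < ng; ++g)
      if (t_react <= grid_times[g]) reacted[g]++;
    if ((rep & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return reacted;
}

// [[Rcpp::export(name = ".bd_cluster_cpp")]]
IntegerMatrix bd_cluster_cpp(NumericMatrix pos, IntegerVector spec0,
                             NumericVector D_spec,
                             IntegerVector ch_a, IntegerVector ch_b,
                             NumericVector ch_R, IntegerVector ch_rid,
                             NumericVector ch_q,
                             IntegerVector fo_spec, NumericVector fo_rate,
                             IntegerVector fo_rid,
                             int n_chan_total,
                             double dt, NumericVector grid_times,
                             int n_rep) {
  // full per-particle propagation; all pairwise encounter tests per step;
  // first-order channels fire on pre-sampled exponential clocks (channel
  // picked proportionally to its rate). Reaction products are NOT
  // re-introduced (oracle restricted to networks with chemically inert
  // products). Returns, per channel row (0-based ids in ch_rid / fo_rid),
  // the number of reaction events that occurred by each grid time.
  int n = pos.nrow(), ng = grid_times.size();
  double t_end = grid_times[ng - 1];
  int nchan = ch_a.size(), nspec = D_spec.size();
  IntegerMatrix out(n_chan_total, ng);
  std::vector<double> sd(n);
  for (int i = 0; i < n; ++i) sd[i] = std::sqrt(2.0 * D_spec[spec0[i]] * dt);

  std::vector<double> lamTot(nspec, 0.0);
  for (int c = 0; c < fo_spec.size(); ++c) lamTot[fo_spec[c]] += fo_rate[c];

  std::vector<double> x(n), y(n), z(n), tfo(n);
  std::vector<int> fo_id(n);
  std::vector<char> alive(n);
  for (int rep = 0; rep < n_rep; ++rep) {
    for (int i = 0; i < n; ++i) {
      x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
      alive[i] = 1;
      double lam = lamTot[spec0[i]];
      if (lam > 0.0) {
        tfo[i] = exp_rand() / lam;
        double v = unif_rand() * lam;
        fo_id[i] = -1;
        for (int c = 0; c < fo_spec.size(); ++c) {
          if (fo_spec[c] != spec0[i]) continue;
          v -= fo_rate[c];
          fo_id[i] = fo_rid[c];
          if (v <= 0.0) break;
        }
      } else {
        tfo[i] = R_PosInf; fo_id[i] = -1;
      }
    }
    double t = 0.0;
    int nalive = n;
    std::vector<double> xo(n), yo(n), zo(n);
    while (t < t_end && nalive > 0) {
      t += dt;
      for (int i = 0; i < n; ++i) if (alive[i]) {
        xo[i] = x[i]; yo[i] = y[i]; zo[i] = z[i];
        x[i] += norm_rand() * sd[i];
        y[i] += norm_rand() * sd[i];
        z[i] += norm_rand() * sd[i];
      }
      for (int c = 0; c < nchan && nalive > 1; ++c) {
        int a = ch_a[c], b = ch_b[c];
        double R = ch_R[c];
        double Dm = D_spec[a] + D_spec[b];
        bool absorbing = !R_finite(ch_q[c]);
        double pstep = absorbing ? 1.0 : -std::expm1(-ch_q[c] * dt);
        for (int i = 0; i < n; ++i) {
          if (!alive[i] || spec0[i] != a) continue;
          for (int j = 0; j < n; ++j) {
            if (j == i || !alive[j] || spec0[j] != b) continue;
            if (a == b && j < i) continue;  // each unordered like pair once
            double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            bool hit = false;
            if (r < R) {
              hit = absorbing || unif_rand() < pstep;
            } else if (absorbing) {
              double dxo = xo[i] - xo[j], dyo = yo[i] - yo[j],
                     dzo = zo[i] - zo[j];
              double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo);
              if (ro > R) {
                double pbridge = std::exp(-(ro - R) * (r - R) / (Dm * dt));
                hit = unif_rand() < pbridge;
              }
            }
            if (hit) {
              alive[i] = alive[j] = 0; nalive -= 2;
              for (int g = 0; g < ng; ++g)
                if (t <= grid_times[g]) out(ch_rid[c], g)++;
              break;
            }
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        if (alive[i] && tfo[i] <= t) {
          alive[i] = 0; nalive -= 1;
          if (fo_id[i] >= 0)
            for (int g = 0; g < ng; ++g)
              if (t <= grid_times[g]) out(fo_id[i], g)++;
        }
      }
    }
    if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
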