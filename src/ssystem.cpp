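#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// S-system rate for gene i at log-state lx (length N):
//   dXi/dt = alpha * prod_j Xj^g[j] - beta * prod_j Xj^h[j]
// computed in log space so that one log() per state component serves both
// power-law products.
static inline double ss_rate(double alpha, double beta,
                             const double *g, const double *h,
                             const double *lx, int N) {
  double sg = 0.0, sh = 0.0;
  for (int j = 0; j < N; ++j) {
    sg += g[j] * lx[j];
    sh += h[j] * lx[j];
  }
  return alpha * std::exp(sg) - beta * std::exp(sh);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_network(NumericVector alpha, NumericVector beta,
                                   NumericMatrix G, NumericMatrix H,
                                   NumericVector x0, NumericVector times,
                                   double dt, double state_floor,
                                   double overflow_ceiling) {
  const int N = x0.size(), T = times.size();
  NumericMatrix out(T, N);
  std::vector<double> x(N), lx(N), xs(N), k1(N), k2(N), k3(N), k4(N);
  std::vector<double> gr(N * N), hr(N * N); // row-major copies: gene i row
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      gr[i * N + j] = G(i, j);
      hr[i * N + j] = H(i, j);
    }

  for (int j = 0; j < N; ++j) {
    x[j] = std::max(x0[j], state_floor);
    out(0, j) = x[j];
  }

  auto rates = [&](const std::vector<double> &xv, std::vector<double> &kv) {
    for (int j = 0; j < N; ++j)
      lx[j] = std::log(std::max(xv[j], state_floor));
    for (int i = 0; i < N; ++i)
      kv[i] = ss_rate(alpha[i], beta[i], &gr[i * N], &hr[i * N], lx.data(), N);
  };

  for (int k = 0; k + 1 < T; ++k) {
    double span = times[k + 1] - times[k];
    int m = (int)std::ceil(span / dt - 1e-9);
    if (m < 1) m = 1;
    double hstep = span / m;
    for (int s = 0; s < m; ++s) {
      rates(x, k1);
      for (int j = 0; j < N; ++j) xs[j] = x[j] + 0.5 * hstep * k1[j];
      rates(xs, k2);
      for (int j = 0; j < N; ++j) xs[j] = x[j] + 0.5 * hstep * k2[j];
      rates(xs, k3);
      for (int j = 0; j < N; ++j) xs[j] = x[j] + hstep * k3[j];
      rates(xs, k4);
      for (int j = 0; j < N; ++j) {
        x[j] += hstep / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (!std::isfinite(x[j]) || x[j] > overflow_ceiling)
          stop("state diverged at time index %d (gene %d)", k + 1, j + 1);
        if (x[j] < state_floor) x[j] = state_floor;
      }
    }
    for (int j = 0; j < N; ++j) out(k + 1, j) = x[j];
  }
  return out;
}

// Decoupled single-gene integration against a precomputed half-step grid of
// log off-target states.  `L` has one row per RK4 stage time (start, mid,
// end of every internal substep; consecutive substeps share rows), column
// `gene` is ignored and replaced by the evolving state.  `m_counts[k]`
// internal substeps of size `h_steps[k]` cover observation interval k.
static bool decoupled_run(const double *theta, int N,
                          const NumericMatrix &L, const IntegerVector &m_counts,
                          const NumericVector &h_steps, const NumericVector &obs,
                          int gene, double state_floor, double overflow_ceiling,
                          double *pred) {
  const double alpha = theta[0], beta = theta[1];
  const double *g = theta + 2, *h = theta + 2 + N;
  const int T = obs.size();
  const double gi = g[gene], hi = h[gene];

  // off-target contributions per stage row depend on the candidate, so fold
  // the candidate's own-gene term in separately from the row dot products
  double x = std::max(obs[0], state_floor);
  pred[0] = x;
  int row = 0;
  for (int k = 0; k + 1 < T; ++k) {
    const int m = m_counts[k];
    const double hstep = h_steps[k];
    for (int s = 0; s < m; ++s) {
      double dg0 = 0.0, dh0 = 0.0, dg1 = 0.0, dh1 = 0.0, dg2 = 0.0, dh2 = 0.0;
      for (int j = 0; j < N; ++j) {
        if (j == gene) continue;
        const double l0 = L(row, j), l1 = L(row + 1, j), l2 = L(row + 2, j);
        dg0 += g[j] * l0; dh0 += h[j] * l0;
        dg1 += g[j] * l1; dh1 += h[j] * l1;
        dg2 += g[j] * l2; dh2 += h[j] * l2;
      }
      auto f = [&](double xi, double dg, double dh) {
        const double lxi = std::log(std::max(xi, state_floor));
        return alpha * std::exp(dg + gi * lxi) - beta * std::exp(dh + hi * lxi);
      };
      const double k1 = f(x, dg0, dh0);
      const double k2 = f(x + 0.5 * hstep * k1, dg1, dh1);
      const double k3 = f(x + 0.5 * hstep * k2, dg1, dh1);
      const double k4 = f(x + hstep * k3, dg2, dh2);
      x += hstep / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!std::isfinite(x) || x > overflow_ceiling) return false;
      if (x < state_floor) x = state_floor;
      row += 2;
    }
    pred[k + 1] = x;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_decoupled_fitness(NumericMatrix cand, NumericMatrix L,
                                    IntegerVector m_counts, NumericVector h_steps,
                                    NumericVector obs, int gene0,
                                    double state_floor, double overflow_ceiling,
                                    double mse_floor, double fail_value) {
  const int n = cand.nrow(), T = obs.size(), N = (cand.ncol() - 2) / 2;
  const int R = L.nrow();
  NumericVector out(n);

  // batch precomputation: per candidate c and stage row r, the off-target
  // contributions dg(r,c) = sum_{j != gene} g_j * L(r,j) (and likewise dh),
  // so the integration loop touches only exp/log and a few multiplies
  std::vector<double> Dg((size_t)R * n), Dh((size_t)R * n);
  for (int c = 0; c < n; ++c) {
    const double *g = &cand(0, 2) + c;          // column-major: row c
    const double *h = &cand(0, 2 + N) + c;
    for (int j = 0; j < N; ++j) {
      if (j == gene0) continue;
      const double gj = g[(size_t)j * n], hj = h[(size_t)j * n];
      if (gj == 0.0 && hj == 0.0) continue;
      const double *Lj = &L(0, j);
      double *dg = &Dg[(size_t)c * R], *dh = &Dh[(size_t)c * R];
      for (int r = 0; r < R; ++r) {
        dg[r] += gj * Lj[r];
        dh[r] += hj * Lj[r];
      }
    }
  }

  std::vector<double> pred(T);
  for (int c = 0; c < n; ++c) {
    const double alpha = cand(c, 0), beta = cand(c, 1);
    const double gi = cand(c, 2 + gene0), hi = cand(c, 2 + N + gene0);
    const double *dg = &Dg[(size_t)c * R], *dh = &Dh[(size_t)c * R];
    double x = std::max(obs[0], state_floor);
    pred[0] = x;
    bool ok = true;
    int row = 0;
    for (int k = 0; k + 1 < T && ok; ++k) {
      const int m = m_counts[k];
      const double hstep = h_steps[k];
      for (int s = 0; s < m; ++s) {
        auto f = [&](double xi, int r) {
          const double lxi = std::log(std::max(xi, state_floor));
          return alpha * std::exp(dg[r] + gi * lxi) -
                 beta * std::exp(dh[r] + hi * lxi);
        };
        const double k1 = f(x, row);
        const double k2 = f(x + 0.5 * hstep * k1, row + 1);
        const double k3 = f(x + 0.5 * hstep * k2, row + 1);
        const double k4 = f(x + hstep * k3, row + 2);
        x += hstep / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
        if (!std::isfinite(x) || x > overflow_ceiling) { ok = false; break; }
        if (x < state_floor) x = state_floor;
        row += 2;
      }
      pred[k + 1] = x;
    }
    if (!ok) { out[c] = fail_value; continue; }
    double err = 0.0;
    for (int t = 0; t < T; ++t) {
      const double denom = std::max(obs[t], mse_floor);
      const double d = (pred[t] - obs[t]) / denom;
      err += d * d;
    }
    out[c] = std::isfinite(err) ? err : fail_value;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_decoupled_traj(NumericVector theta, NumericMatrix L,
                                 IntegerVector m_counts, NumericVector h_steps,
                                 NumericVector obs, int gene0,
                                 double state_floor, double overflow_ceiling) {
  const int T = obs.size(), N = (theta.size() - 2) / 2;
  NumericVector pred(T);
  bool ok = decoupled_run(REAL(theta), N, L, m_counts, h_steps, obs, gene0,
                          state_floor, overflow_ceiling, REAL(pred));
  if (!ok)
    stop("decoupled simulation of gene %d diverged", gene0 + 1);
  return pred;
}
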