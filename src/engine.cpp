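// Fast kernels for the vocal-development simulator:
//  - lossless concatenated-tube resonance search (surrogate formants)
//  - closed-form overdamped spring-mass segment evaluation
//  - batched execution of goal-directed vocalization epochs
// All random draws go through R's RNG (unif_rand / norm_rand) so that
// set.seed() in R makes every run bit-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tube acoustics
// ---------------------------------------------------------------------------

// Characteristic function whose zeros (in frequency) are the resonances of a
// chain of equal-length lossless tube sections, closed at the glottis and
// open (pressure release) at the lips. We propagate (scaled pressure a,
// volume velocity b) from the lips toward the glottis; a resonance occurs
// when the glottal volume velocity b vanishes. s, c are sin/cos of k*l for
// the shared section length.
static inline double tube_char_sc(const double* areas, int K, double s, double c) {
  double a = 0.0, b = 1.0; // lips boundary: p = 0, U = 1
  for (int j = K - 1; j >= 0; --j) {
    double A  = areas[j];
    double an = c * a + (s / A) * b;
    double bn = -A * s * a + c * b;
    a = an;
    b = bn;
  }
  return b;
}

static inline double tube_char(const double* areas, int K, double sec_len,
                               double c_sound, double f) {
  double k = 2.0 * M_PI * f / c_sound;
  return tube_char_sc(areas, K, std::sin(k * sec_len), std::cos(k * sec_len));
}

// First two resonances by grid scan + bisection. gs/gc hold precomputed
// sin/cos of k*l on the grid. Missing resonances (degenerate tracts) are
// reported at the upper scan edge; downstream scaling clips them.
static void tube_first_two(const double* areas, int K, double sec_len,
                           double c_sound, const double* grid,
                           const double* gs, const double* gc, int ng,
                           double* out) {
  int found = 0;
  double prev = tube_char_sc(areas, K, gs[0], gc[0]);
  for (int i = 1; i < ng && found < 2; ++i) {
    double cur = tube_char_sc(areas, K, gs[i], gc[i]);
    if (cur == 0.0) {
      out[found++] = grid[i];
    } else if ((prev > 0.0) != (cur > 0.0)) {
      double lo = grid[i - 1], hi = grid[i], flo = prev;
      for (int it = 0; it < 40; ++it) {
        double mid = 0.5 * (lo + hi);
        double fm  = tube_char(areas, K, sec_len, c_sound, mid);
        if ((flo > 0.0) != (fm > 0.0)) {
          hi = mid;
        } else {
          lo = mid;
          flo = fm;
        }
      }
      out[found++] = 0.5 * (lo + hi);
    }
    prev = cur;
  }
  while (found < 2) out[found++] = grid[ng - 1];
}

// [[Rcpp::export]]
NumericMatrix tube_formants_cpp(NumericMatrix areas, double sec_len,
                                double c_sound, NumericVector grid) {
  int n = areas.nrow(), K = areas.ncol(), ng = grid.size();
  std::vector<double> gs(ng), gc(ng);
  for (int i = 0; i < ng; ++i) {
    double k = 2.0 * M_PI * grid[i] / c_sound;
    gs[i] = std::sin(k * sec_len);
    gc[i] = std::cos(k * sec_len);
  }
  NumericMatrix out(n, 2);
  std::vector<double> row(K);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < K; ++j) row[j] = areas(i, j);
    double f[2];
    tube_first_two(row.data(), K, sec_len, c_sound, grid.begin(), gs.data(),
                   gc.data(), ng, f);
    out(i, 0) = f[0];
    out(i, 1) = f[1];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped spring-mass closed form
// ---------------------------------------------------------------------------

// x(t) = m + A exp(r1 t) + B exp(r2 t), with A, B fixed by (x0, v0).
static inline void seg_coef(double x0, double v0, double m, double r1,
                            double r2, double& A, double& B) {
  double D = x0 - m;
  A = (v0 - r2 * D) / (r1 - r2);
  B = D - A;
}

// ---------------------------------------------------------------------------
// Shared synthesis of one policy at the perception-window samples
// ---------------------------------------------------------------------------

struct SynthPars {
  const double* a0;     // neutral area profile (K)
  const double* basis;  // K x 7, column-major
  int K;
  double sec_len, c_sound;
  double f1_lo, f1_hi, f2_lo, f2_hi;
  const double* grid;
  const double* gs;
  const double* gc;
  int ng;
  // dynamics
  double r1, r2;
  double e1_s1, e2_s1;  // exp(r * switch_time) for segment 1
  const double* e1_w;   // exp(r1 * (t - switch)) at window samples
  const double* e2_w;
  int n_w, n_w1;        // total window samples, count in window 1
  const double* x_init; // 9-dim start state
  bool pv_onset_command; // pressure/voicing start at their first command
};

// Computes the pre-noise 6-dim outcome [I1, I2, F11, F12, F21, F22] of an
// 18-dim policy (m1, m2).
static void policy_outcome(const double* m, const SynthPars& P, double* s6) {
  double A2[9], B2[9], m2v[9];
  for (int d = 0; d < 9; ++d) {
    double m1 = m[d], m2 = m[d + 9];
    double x25, v25;
    if (P.pv_onset_command && d >= 7) {
      x25 = m1; // glottal parameters act fast: held at the first command
      v25 = 0.0;
    } else {
      double A1, B1;
      seg_coef(P.x_init[d], 0.0, m1, P.r1, P.r2, A1, B1);
      x25 = m1 + A1 * P.e1_s1 + B1 * P.e2_s1;
      v25 = A1 * P.r1 * P.e1_s1 + B1 * P.r2 * P.e2_s1;
    }
    seg_coef(x25, v25, m2, P.r1, P.r2, A2[d], B2[d]);
    m2v[d] = m2;
  }
  double isum[2] = {0.0, 0.0}, f1sum[2] = {0.0, 0.0}, f2sum[2] = {0.0, 0.0};
  std::vector<double> areas(P.K);
  for (int w = 0; w < P.n_w; ++w) {
    int win = (w < P.n_w1) ? 0 : 1;
    double st[9];
    for (int d = 0; d < 9; ++d)
      st[d] = m2v[d] + A2[d] * P.e1_w[w] + B2[d] * P.e2_w[w];
    double pres = st[7], voic = st[8];
    if (pres > 0.0 && voic > 0.0) {
      double amin = 1e300;
      for (int j = 0; j < P.K; ++j) {
        double a = P.a0[j];
        for (int q = 0; q < 7; ++q) a += P.basis[j + q * P.K] * st[q];
        areas[j] = a > 0.0 ? a : 0.0;
        if (a < amin) amin = a;
      }
      if (amin > 0.0) { // open tract: phonation
        double f[2];
        tube_first_two(areas.data(), P.K, P.sec_len, P.c_sound, P.grid, P.gs,
                       P.gc, P.ng, f);
        double f1s = 2.0 * (f[0] - P.f1_lo) / (P.f1_hi - P.f1_lo) - 1.0;
        double f2s = 2.0 * (f[1] - P.f2_lo) / (P.f2_hi - P.f2_lo) - 1.0;
        f1s = std::min(1.0, std::max(-1.0, f1s));
        f2s = std::min(1.0, std::max(-1.0, f2s));
        isum[win] += 1.0;
        f1sum[win] += f1s;
        f2sum[win] += f2s;
      }
    }
  }
  double nw[2] = {double(P.n_w1), double(P.n_w - P.n_w1)};
  s6[0] = isum[0] / nw[0];
  s6[1] = isum[1] / nw[1];
  s6[2] = f1sum[0] / nw[0];
  s6[3] = f1sum[1] / nw[1];
  s6[4] = f2sum[0] / nw[0];
  s6[5] = f2sum[1] / nw[1];
}

static SynthPars make_pars(const arma::vec& a0, const arma::mat& basis,
                           double sec_len, double c_sound,
                           const arma::vec& fr, const arma::vec& grid,
                           const std::vector<double>& gs,
                           const std::vector<double>& gc, double r1, double r2,
                           double switch_time, const arma::vec& e1_w,
                           const arma::vec& e2_w, int n_w1,
                           const arma::vec& x_init, bool pv_onset_command) {
  SynthPars P;
  P.a0 = a0.memptr();
  P.basis = basis.memptr();
  P.K = a0.n_elem;
  P.sec_len = sec_len;
  P.c_sound = c_sound;
  P.f1_lo = fr[0];
  P.f1_hi = fr[1];
  P.f2_lo = fr[2];
  P.f2_hi = fr[3];
  P.grid = grid.memptr();
  P.gs = gs.data();
  P.gc = gc.data();
  P.ng = grid.n_elem;
  P.r1 = r1;
  P.r2 = r2;
  P.e1_s1 = std::exp(r1 * switch_time);
  P.e2_s1 = std::exp(r2 * switch_time);
  P.e1_w = e1_w.memptr();
  P.e2_w = e2_w.memptr();
  P.n_w = e1_w.n_elem;
  P.n_w1 = n_w1;
  P.x_init = x_init.memptr();
  P.pv_onset_command = pv_onset_command;
  return P;
}

static void grid_trig(const arma::vec& grid, double sec_len, double c_sound,
                      std::vector<double>& gs, std::vector<double>& gc) {
  int ng = grid.n_elem;
  gs.resize(ng);
  gc.resize(ng);
  for (int i = 0; i < ng; ++i) {
    double k = 2.0 * M_PI * grid[i] / c_sound;
    gs[i] = std::sin(k * sec_len);
    gc[i] = std::cos(k * sec_len);
  }
}

// Execute a batch of fixed policies (rows of M); returns pre-noise and noisy
// outcomes. Used for agent initialization, teacher construction and the
// plain `vocalize` path.
// [[Rcpp::export]]
List synthesize_batch_cpp(const arma::mat& M, const arma::vec& a0,
                          const arma::mat& basis, double sec_len,
                          double c_sound, const arma::vec& formant_ranges,
                          const arma::vec& grid, double r1, double r2,
                          double switch_time, const arma::vec& e1_w,
                          const arma::vec& e2_w, int n_w1,
                          const arma::vec& x_init, double noise_sd,
                          bool pv_onset_command) {
  int n = M.n_rows;
  std::vector<double> gs, gc;
  grid_trig(grid, sec_len, c_sound, gs, gc);
  SynthPars P = make_pars(a0, basis, sec_len, c_sound, formant_ranges, grid,
                          gs, gc, r1, r2, switch_time, e1_w, e2_w, n_w1,
                          x_init, pv_onset_command);
  arma::mat pre(n, 6), out(n, 6);
  double s6[6];
  for (int i = 0; i < n; ++i) {
    arma::rowvec mi = M.row(i);
    policy_outcome(mi.memptr(), P, s6);
    for (int j = 0; j < 6; ++j) {
      pre(i, j) = s6[j];
      out(i, j) = s6[j] + (noise_sd > 0.0 ? noise_sd * norm_rand() : 0.0);
    }
  }
  return List::create(_["prenoise"] = pre, _["s"] = out);
}

// ---------------------------------------------------------------------------
// GMM helpers
// ---------------------------------------------------------------------------

// Per-component log-densities log N(x_i; mu_k, Sigma_k), given lower
// Cholesky factors. X: n x d; mu: d x k; L: d x d x k.
// [[Rcpp::export]]
arma::mat gmm_comp_logdens_cpp(const arma::mat& X, const arma::mat& mu,
                               const arma::cube& L) {
  int n = X.n_rows, d = X.n_cols, k = mu.n_cols;
  arma::mat out(n, k);
  double c0 = -0.5 * d * std::log(2.0 * M_PI);
  for (int j = 0; j < k; ++j) {
    arma::mat Lj = L.slice(j);
    double ldet = arma::sum(arma::log(Lj.diag()));
    arma::mat Z = arma::solve(arma::trimatl(Lj),
                              X.t() - arma::repmat(mu.col(j), 1, n));
    out.col(j) = (c0 - ldet - 0.5 * arma::sum(arma::square(Z), 0).t());
  }
  return out;
}

// Forward substitution for a single 6-ish dim system; returns quadratic form.
static inline double quad_lower(const arma::mat& L, const double* y, int d,
                                double* z) {
  double q = 0.0;
  for (int i = 0; i < d; ++i) {
    double acc = y[i];
    for (int j = 0; j < i; ++j) acc -= L(i, j) * z[j];
    z[i] = acc / L(i, i);
    q += z[i] * z[i];
  }
  return q;
}

// ---------------------------------------------------------------------------
// Exploration epoch
// ---------------------------------------------------------------------------

// Runs n_iter goal-directed vocalizations against frozen models:
//  - goal (and optional strategy) sampled from the biased interest mixture
//  - motor policy sampled from the conditional G_SM(M | s_g)
//  - policy executed through dynamics + synthesizer + windowed perception
//  - Gaussian observation noise added to the 6-dim outcome
// Model updates happen in R between epochs.
// Argument groups: interest sampling mixture (strategy coordinate first if
// any); sensorimotor conditional cache; synthesizer + dynamics + perception.
// [[Rcpp::export]]
List run_epoch_cpp(int n_iter,
                   const arma::vec& im_w, const arma::mat& im_mu,
                   const arma::cube& im_chol, bool with_strategy,
                   bool strategy_uniform,
                   double strategy_threshold, const arma::vec& goal_lo,
                   const arma::vec& goal_hi, const arma::mat& demos,
                   const arma::vec& sm_lw0, const arma::mat& sm_muS,
                   const arma::cube& sm_LS, const arma::mat& sm_muM,
                   const arma::cube& sm_K, const arma::cube& sm_LC,
                   const arma::vec& m_lo, const arma::vec& m_hi,
                   const arma::vec& a0, const arma::mat& basis,
                   double sec_len, double c_sound,
                   const arma::vec& formant_ranges, const arma::vec& grid,
                   double r1, double r2, double switch_time,
                   const arma::vec& e1_w, const arma::vec& e2_w, int n_w1,
                   const arma::vec& x_init, double noise_sd,
                   bool pv_onset_command) {
  int kim = im_w.n_elem, ksm = sm_lw0.n_elem;
  int dS = 6, dM = 18;
  std::vector<double> gs, gc;
  grid_trig(grid, sec_len, c_sound, gs, gc);
  SynthPars P = make_pars(a0, basis, sec_len, c_sound, formant_ranges, grid,
                          gs, gc, r1, r2, switch_time, e1_w, e2_w, n_w1,
                          x_init, pv_onset_command);

  arma::mat Mout(n_iter, dM), Sg(n_iter, dS), Sout(n_iter, dS);
  arma::ivec strat(n_iter, arma::fill::zeros);

  int dG = im_mu.n_rows; // 6, or 7 with leading strategy coordinate
  arma::vec cumw = arma::cumsum(im_w);
  std::vector<double> g(dG), zg(dG), goal(dS), y(dS), zs(dS), logw(ksm),
      m18(dM), s6(6);

  for (int t = 0; t < n_iter; ++t) {
    // -- goal / strategy
    double u = unif_rand() * cumw[kim - 1];
    int j = 0;
    while (j < kim - 1 && u > cumw[j]) ++j;
    for (int d = 0; d < dG; ++d) zg[d] = norm_rand();
    const arma::mat& Lg = im_chol.slice(j);
    for (int d = 0; d < dG; ++d) {
      double acc = im_mu(d, j);
      for (int q = 0; q <= d; ++q) acc += Lg(d, q) * zg[q];
      g[d] = acc;
    }
    int st = 0;
    int off = with_strategy ? 1 : 0;
    if (with_strategy) {
      if (strategy_uniform) // no strategy shows progress: equal probability
        st = (unif_rand() < 0.5) ? 1 : 0;
      else if (g[0] > strategy_threshold)
        st = 1;
    }
    if (st == 1 && demos.n_rows > 0) {
      int di = std::min<int>(demos.n_rows - 1,
                             int(unif_rand() * demos.n_rows));
      for (int d = 0; d < dS; ++d) goal[d] = demos(di, d);
    } else {
      for (int d = 0; d < dS; ++d) {
        double v = g[d + off];
        goal[d] = std::min(goal_hi[d], std::max(goal_lo[d], v));
      }
    }
    strat[t] = st;
    for (int d = 0; d < dS; ++d) Sg(t, d) = goal[d];

    // -- conditional weights over G_SM components
    double mx = -1e300;
    for (int c = 0; c < ksm; ++c) {
      for (int d = 0; d < dS; ++d) y[d] = goal[d] - sm_muS(d, c);
      double q = quad_lower(sm_LS.slice(c), y.data(), dS, zs.data());
      logw[c] = sm_lw0[c] - 0.5 * q;
      if (logw[c] > mx) mx = logw[c];
    }
    double tot = 0.0;
    for (int c = 0; c < ksm; ++c) {
      logw[c] = std::exp(logw[c] - mx);
      tot += logw[c];
    }
    double u2 = unif_rand() * tot;
    int cj = 0;
    double acc = logw[0];
    while (cj < ksm - 1 && u2 > acc) acc += logw[++cj];

    // -- conditional mean + draw
    const arma::mat& Kc = sm_K.slice(cj);
    const arma::mat& Lc = sm_LC.slice(cj);
    for (int d = 0; d < dS; ++d) y[d] = goal[d] - sm_muS(d, cj);
    double zm[18];
    for (int d = 0; d < dM; ++d) zm[d] = norm_rand();
    for (int d = 0; d < dM; ++d) {
      double v = sm_muM(d, cj);
      for (int q = 0; q < dS; ++q) v += Kc(d, q) * y[q];
      for (int q = 0; q <= d; ++q) v += Lc(d, q) * zm[q];
      v = std::min(m_hi[d], std::max(m_lo[d], v));
      m18[d] = v;
      Mout(t, d) = v;
    }

    // -- execute + perceive
    policy_outcome(m18.data(), P, s6.data());
    for (int d = 0; d < dS; ++d)
      Sout(t, d) = s6[d] + (noise_sd > 0.0 ? noise_sd * norm_rand() : 0.0);
  }
  return List::create(_["m"] = Mout, _["s_g"] = Sg, _["s"] = Sout,
                      _["strategy"] = strat);
}
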