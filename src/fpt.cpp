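#include <Rcpp.h>
using namespace Rcpp;

// Forward (Fokker-Planck) solution of dx = mu dt + sigma dW, sigma = 1,
// between absorbing bounds at +/- (B - tB * t), starting at x0c (internal
// coordinates, 0 = midpoint). Theta-scheme in time (backward Euler during
// the Rannacher startup and whenever the bound is collapsing, otherwise
// Crank-Nicolson), central differences in space; probability mass is
// tracked per grid cell so absorbed + undecided mass is conserved
// exactly. Fills per-step absorbed-mass densities into dup/dlo (length
// K) and returns the undecided mass.
static double fpt_run(double mu, double B, double tB, double x0c,
                      double window, double dt, double dx,
                      std::vector<double> &dup, std::vector<double> &dlo,
                      int &K_out) {
  const int N = std::max(4, (int)std::lround(2.0 * B / dx));
  const double h = 2.0 * B / N;
  const int K = (int)std::ceil(window / dt);
  K_out = K;
  dup.assign(K, 0.0);
  dlo.assign(K, 0.0);

  std::vector<double> m(N + 1, 0.0);
  double pos = (x0c + B) / h;
  int j0 = (int)std::floor(pos);
  if (j0 < 1) j0 = 1;
  if (j0 > N - 2) j0 = N - 2;
  double w = pos - j0;
  m[j0] += 1.0 - w;
  m[j0 + 1] += w;

  const double D = 0.5;
  const double cdiff = D * dt / (h * h);
  const double cadv = mu * dt / (2.0 * h);
  const double aL = cdiff + cadv, aD = -2.0 * cdiff, aU = cdiff - cadv;

  double absorbed_up = 0.0, absorbed_lo = 0.0;
  std::vector<double> rhs(N + 1), dpr(N + 1), cpr(N + 1);
  for (int k = 1; k <= K; ++k) {
    double t_new = k * dt;
    double up_step = 0.0, lo_step = 0.0;
    double b_new = B - tB * t_new;
    int lo_idx = (int)std::floor((B - b_new) / h) + 1;
    int hi_idx = N - lo_idx;
    if (b_new <= h || lo_idx >= hi_idx) {
      for (int j = 0; j <= N; ++j) {
        if (m[j] <= 0.0) continue;
        double x = -B + j * h;
        if (x > 1e-12) up_step += m[j];
        else if (x < -1e-12) lo_step += m[j];
        else { up_step += 0.5 * m[j]; lo_step += 0.5 * m[j]; }
        m[j] = 0.0;
      }
      dup[k - 1] = up_step / dt;
      dlo[k - 1] = lo_step / dt;
      absorbed_up += up_step; absorbed_lo += lo_step;
      break;
    }
    for (int j = 1; j < lo_idx; ++j) { lo_step += m[j]; m[j] = 0.0; }
    for (int j = hi_idx + 1; j < N; ++j) { up_step += m[j]; m[j] = 0.0; }
    double mass_before = 0.0;
    for (int j = lo_idx; j <= hi_idx; ++j) mass_before += m[j];
    if (mass_before <= 1e-12) {
      absorbed_up += up_step; absorbed_lo += lo_step;
      dup[k - 1] = up_step / dt;
      dlo[k - 1] = lo_step / dt;
      break;  // nothing left to absorb
    }
    double th = (k <= 8 || tB > 0.0) ? 1.0 : 0.5;
    double ex = 1.0 - th;
    for (int j = lo_idx; j <= hi_idx; ++j) {
      double pm = (j - 1 >= lo_idx) ? m[j - 1] : 0.0;
      double pp = (j + 1 <= hi_idx) ? m[j + 1] : 0.0;
      rhs[j] = m[j] + ex * (aL * pm + aD * m[j] + aU * pp);
    }
    double sub = -th * aL, dia = 1.0 - th * aD, sup = -th * aU;
    cpr[lo_idx] = sup / dia;
    dpr[lo_idx] = rhs[lo_idx] / dia;
    for (int j = lo_idx + 1; j <= hi_idx; ++j) {
      double denom = dia - sub * cpr[j - 1];
      cpr[j] = sup / denom;
      dpr[j] = (rhs[j] - sub * dpr[j - 1]) / denom;
    }
    m[hi_idx] = dpr[hi_idx];
    for (int j = hi_idx - 1; j >= lo_idx; --j) m[j] = dpr[j] - cpr[j] * m[j + 1];
    double mass_after = 0.0;
    for (int j = lo_idx; j <= hi_idx; ++j) mass_after += m[j];
    double lost = mass_before - mass_after;
    if (lost < 0.0) lost = 0.0;
    double mu_p = mu > 0.0 ? mu : 0.0, mu_n = mu < 0.0 ? -mu : 0.0;
    double p_hi = m[hi_idx] / h, p_lo = m[lo_idx] / h;
    double flux_up = D * p_hi / h + mu_p * p_hi;
    double flux_lo = D * p_lo / h + mu_n * p_lo;
    double tot = flux_up + flux_lo;
    double fu = (tot > 0.0) ? flux_up / tot : 0.5;
    up_step += lost * fu;
    lo_step += lost * (1.0 - fu);
    absorbed_up += up_step; absorbed_lo += lo_step;
    dup[k - 1] = up_step / dt;
    dlo[k - 1] = lo_step / dt;
  }
  double undec = 1.0 - absorbed_up - absorbed_lo;
  return undec < 0.0 ? 0.0 : undec;
}

// Grouped likelihood evaluation: trials sorted so that equal `group`
// values are contiguous; one first-passage solve per group, then linear
// interpolation of the defect density at each trial's decision time.
// upper[i]: 1 if the trial's choice is the upper (high) bound.
// Returns per-trial DDM-component densities (no lapse mixing).
// [[Rcpp::export]]
NumericVector fpt_group_density_cpp(IntegerVector group, NumericVector mu,
                                    NumericVector x0c, NumericVector B,
                                    NumericVector tB, NumericVector window,
                                    NumericVector td, IntegerVector upper,
                                    double dt, double dx) {
  int n = group.size();
  NumericVector out(n);
  std::vector<double> dup, dlo;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && group[j] == group[i]) ++j;
    // solve only as far as the group's latest decision time needs
    double tmax = 0.0;
    for (int r = i; r < j; ++r) if (td[r] > tmax) tmax = td[r];
    double weff = std::min(window[i], tmax + 2.0 * dt);
    if (weff <= dt) weff = dt;
    int K = 0;
    fpt_run(mu[i], B[i], tB[i], x0c[i], weff, dt, dx, dup, dlo, K);
    for (int r = i; r < j; ++r) {
      double t = td[r];
      if (t <= 0.0 || t > K * dt) { out[r] = 0.0; continue; }
      const std::vector<double> &dens = upper[r] ? dup : dlo;
      // density array value k represents absorption over ((k)dt,(k+1)dt];
      // interpolate on midpoints
      double pos = t / dt - 0.5;
      int k0 = (int)std::floor(pos);
      double frac = pos - k0;
      double v0 = (k0 < 0) ? dens[0] : dens[std::min(k0, K - 1)];
      double v1 = dens[std::min(k0 + 1, K - 1)];
      if (k0 < 0) { v1 = dens[0]; frac = 0.0; }
      out[r] = v0 + frac * (v1 - v0);
    }
    i = j;
  }
  return out;
}

// Full first-passage solution (time grid + defect densities), the
// backend of solve_fpt().
// [[Rcpp::export]]
List fpt_solve_cpp(double mu, double B, double tB, double x0c,
                    double window, double dt, double dx) {
  std::vector<double> dup, dlo;
  int K = 0;
  double undec = fpt_run(mu, B, tB, x0c, window, dt, dx, dup, dlo, K);
  NumericVector tgrid(K), du(K), dl(K);
  double pu = 0.0, pl = 0.0;
  for (int k = 0; k < K; ++k) {
    tgrid[k] = (k + 1) * dt;
    du[k] = dup[k];
    dl[k] = dlo[k];
    pu += dup[k] * dt;
    pl += dlo[k] * dt;
  }
  return List::create(_["time"] = tgrid,
                      _["dens_upper"] = du,
                      _["dens_lower"] = dl,
                      _["p_upper"] = pu,
                      _["p_lower"] = pl,
                      _["undecided"] = undec,
                      _["dt"] = dt);
}

// Euler-Maruyama simulation of one trial per row. Uses R's RNG, so results
// are reproducible under set.seed(). choice: +1 upper, -1 lower, 0 none.
// [[Rcpp::export]]
List ddm_sim_cpp(NumericVector mu, NumericVector x0c, NumericVector B,
                 NumericVector tB, NumericVector window, double dt_sim) {
  int n = mu.size();
  IntegerVector choice(n);
  NumericVector ts(n);
  RNGScope scope;
  double sdt = std::sqrt(dt_sim);
  for (int i = 0; i < n; ++i) {
    double x = x0c[i], t = 0.0;
    int ch = 0;
    double tend = window[i];
    while (t < tend) {
      t += dt_sim;
      x += mu[i] * dt_sim + sdt * norm_rand();
      double b = B[i] - tB[i] * t;
      if (b <= 0.0) { ch = (x > 0.0) ? 1 : (x < 0.0 ? -1 : (unif_rand() < 0.5 ? 1 : -1)); break; }
      if (x >= b) { ch = 1; break; }
      if (x <= -b) { ch = -1; break; }
    }
    choice[i] = ch;
    ts[i] = (ch == 0) ? NA_REAL : t;
  }
  return List::create(_["choice"] = choice, _["t_s"] = ts);
}
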