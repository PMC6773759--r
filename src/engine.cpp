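#include <Rcpp.h>
using namespace Rcpp;

// Fast simulation engine. One immune cell pursues N targets for n_steps on
// the periodic L_sys x L_sys plane. Consumes R's global RNG stream in
// exactly the same order as the pure-R reference engine (per live target:
// width, angle, sign; immune: mode, turn sign, width, angle), so both
// engines reproduce identical trajectories from the same seed.

static inline double wrap_angle(double phi) {
  return phi - 2.0 * M_PI * std::floor((phi + M_PI) / (2.0 * M_PI));
}

static inline double fold1(double x, double L) {
  return x - L * std::floor(x / L);
}

static inline double min_image(double ax, double ay, double bx, double by,
                               double L) {
  double dx = bx - ax, dy = by - ay;
  dx -= L * std::floor(dx / L + 0.5);
  dy -= L * std::floor(dy / L + 0.5);
  return std::sqrt(dx * dx + dy * dy);
}

// log-linear interpolation of the tabulated kernel; clamp below r_tar,
// zero beyond r_max (matches kernel_value()). The radial grid is geometric,
// so the bracketing interval follows from a single logarithm; a local
// correction absorbs floating-point rounding of the index.
static inline double kern(const NumericVector& rg, const NumericVector& lf,
                          double r_tar, double r_max, double r) {
  if (r < r_tar) return 1.0;
  if (r >= r_max) return 0.0;
  const int n = rg.size() - 1;
  int lo = (int)std::floor(n * std::log(r / r_tar) / std::log(r_max / r_tar));
  if (lo < 0) lo = 0;
  if (lo > n - 1) lo = n - 1;
  while (lo > 0 && rg[lo] > r) --lo;
  while (lo < n - 1 && rg[lo + 1] <= r) ++lo;
  double t = (r - rg[lo]) / (rg[lo + 1] - rg[lo]);
  return std::exp(lf[lo] + t * (lf[lo + 1] - lf[lo]));
}

static inline double field(const NumericVector& rg, const NumericVector& lf,
                           double r_tar, double r_max,
                           const std::vector<double>& tx,
                           const std::vector<double>& ty,
                           const std::vector<bool>& alive,
                           double px, double py, double L) {
  double s = 0.0;
  for (size_t c = 0; c < tx.size(); ++c) {
    if (!alive[c]) continue;
    double d = min_image(px, py, tx[c], ty[c], L);
    s += kern(rg, lf, r_tar, r_max, d);
  }
  return s;
}

static inline double logistic_cpp(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double rayleigh_width(double v) {
  double u = unif_rand();
  return v * std::sqrt(2.0 / M_PI) * std::sqrt(-2.0 * std::log(u));
}

static inline double turn_draw(double eps) {
  double lo, hi;
  if (eps >= 0) { lo = -(1.0 - eps) * M_PI; hi = (1.0 - eps) * M_PI; }
  else { lo = (1.0 - std::fabs(eps)) * M_PI; hi = (1.0 + std::fabs(eps)) * M_PI; }
  return lo + unif_rand() * (hi - lo);
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericVector imm_pos, double imm_heading,
                        NumericMatrix tar_pos, NumericVector tar_heading,
                        NumericVector tar_v, NumericVector tar_eps,
                        NumericVector strat, double L_sys, int n_steps,
                        double contact_dist, double r_imm,
                        NumericVector kernel_r, NumericVector kernel_logf,
                        double kernel_rtar, double kernel_rmax,
                        bool record, bool remove_on_contact) {
  const double v_N = strat[0], eps_N = strat[1], v_A = strat[2],
               eps_A = strat[3], c_A0 = strat[4], c_A1 = strat[5],
               c_R1 = strat[6];
  const int N = tar_pos.nrow();

  double ix = imm_pos[0], iy = imm_pos[1];
  double iux = ix, iuy = iy;
  double ih = imm_heading;
  std::vector<double> tx(N), ty(N), tux(N), tuy(N), th(N);
  std::vector<bool> alive(N, true), contacted(N, false);
  for (int c = 0; c < N; ++c) {
    tx[c] = tar_pos(c, 0); ty[c] = tar_pos(c, 1);
    tux[c] = tx[c]; tuy[c] = ty[c];
    th[c] = tar_heading[c];
  }

  double rho_prev = 0.0;
  bool sensor_init = false;

  std::vector<int> contact_step, contact_id;
  std::vector<double> contact_x, contact_y;

  NumericMatrix imm_traj;
  NumericMatrix tarx, tary;
  IntegerVector modes;
  LogicalMatrix alive_rec;
  if (record) {
    imm_traj = NumericMatrix(n_steps + 1, 4);
    tarx = NumericMatrix(n_steps + 1, N);
    tary = NumericMatrix(n_steps + 1, N);
    alive_rec = LogicalMatrix(n_steps + 1, N);
    modes = IntegerVector(n_steps + 1, NA_INTEGER);
    imm_traj(0, 0) = ix; imm_traj(0, 1) = iy;
    imm_traj(0, 2) = iux; imm_traj(0, 3) = iuy;
    for (int c = 0; c < N; ++c) {
      tarx(0, c) = tx[c]; tary(0, c) = ty[c]; alive_rec(0, c) = true;
    }
  }

  for (int n = 1; n <= n_steps; ++n) {
    // (1) all live targets advance (q_R = 1/2, unbiased)
    for (int c = 0; c < N; ++c) {
      if (!alive[c]) continue;
      double w = rayleigh_width(tar_v[c]);
      double dphi = turn_draw(tar_eps[c]);
      double s = (unif_rand() < 0.5) ? -1.0 : 1.0;
      double phi = wrap_angle(th[c] + s * std::fabs(dphi));
      th[c] = phi;
      double dx = w * std::cos(phi), dy = w * std::sin(phi);
      tux[c] += dx; tuy[c] += dy;
      tx[c] = fold1(tx[c] + dx, L_sys);
      ty[c] = fold1(ty[c] + dy, L_sys);
    }

    // (2) immune sensing: temporal difference -> mode, spatial -> sign
    double rho_C = field(kernel_r, kernel_logf, kernel_rtar, kernel_rmax,
                         tx, ty, alive, ix, iy, L_sys);
    double delta_C = sensor_init ? (rho_C - rho_prev) : 0.0;
    rho_prev = rho_C; sensor_init = true;
    double q_A = logistic_cpp(c_A0 + c_A1 * delta_C);
    bool approach = (unif_rand() < q_A);

    double lx = ix + r_imm * std::cos(ih + M_PI / 2.0);
    double ly = iy + r_imm * std::sin(ih + M_PI / 2.0);
    double rx = ix + r_imm * std::cos(ih - M_PI / 2.0);
    double ry = iy + r_imm * std::sin(ih - M_PI / 2.0);
    double delta_LR =
      field(kernel_r, kernel_logf, kernel_rtar, kernel_rmax,
            tx, ty, alive, rx, ry, L_sys) -
      field(kernel_r, kernel_logf, kernel_rtar, kernel_rmax,
            tx, ty, alive, lx, ly, L_sys);
    double q_R = logistic_cpp(c_R1 * delta_LR);
    double s_imm = (unif_rand() < q_R) ? -1.0 : 1.0;

    // (3) immune advances with the chosen mode's speed and persistence
    double v = approach ? v_A : v_N;
    double eps = approach ? eps_A : eps_N;
    double w = rayleigh_width(v);
    double dphi = turn_draw(eps);
    ih = wrap_angle(ih + s_imm * std::fabs(dphi));
    double dx = w * std::cos(ih), dy = w * std::sin(ih);
    iux += dx; iuy += dy;
    ix = fold1(ix + dx, L_sys);
    iy = fold1(iy + dy, L_sys);

    // (4) contact detection at step endpoints; contacted targets removed
    // (or, in the observation regime, kept and flagged on first contact)
    for (int c = 0; c < N; ++c) {
      if (!alive[c] || contacted[c]) continue;
      if (min_image(ix, iy, tx[c], ty[c], L_sys) <= contact_dist) {
        contacted[c] = true;
        if (remove_on_contact) alive[c] = false;
        contact_step.push_back(n);
        contact_id.push_back(c + 1);
        contact_x.push_back(tx[c]);
        contact_y.push_back(ty[c]);
      }
    }

    if (record) {
      imm_traj(n, 0) = ix; imm_traj(n, 1) = iy;
      imm_traj(n, 2) = iux; imm_traj(n, 3) = iuy;
      modes[n] = approach ? 1 : 0;
      for (int c = 0; c < N; ++c) {
        alive_rec(n, c) = alive[c];
        tarx(n, c) = alive[c] ? tx[c] : NA_REAL;
        tary(n, c) = alive[c] ? ty[c] : NA_REAL;
      }
    }
  }

  int Q = 0;
  for (int c = 0; c < N; ++c) if (contacted[c]) ++Q;

  List out = List::create(
    _["Q"] = Q,
    _["contact_step"] = wrap(contact_step),
    _["contact_target"] = wrap(contact_id),
    _["contact_x"] = wrap(contact_x),
    _["contact_y"] = wrap(contact_y));
  if (record) {
    out["immune_trajectory"] = imm_traj;
    out["mode"] = modes;
    out["target_x"] = tarx;
    out["target_y"] = tary;
    out["alive"] = alive_rec;
  }
  return out;
}
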