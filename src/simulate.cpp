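#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-state (free / short-bound / long-bound) Brownian dynamics of
// independent molecules inside a reflecting circular nucleus, observed
// through a camera model (localization noise, per-frame bleaching,
// motion-blur loss in slow-dwell mode).
//
// All randomness flows through R's RNG so that set.seed() in R gives
// bit-identical output.

static const int ST_FREE = 0, ST_SHORT = 1, ST_LONG = 2;

static inline int region_at(double x, double y, const IntegerMatrix &grid,
                            double px, double ox, double oy, bool has_map) {
  if (!has_map) return 0;
  // origin (ox, oy) is the upper-left corner of pixel (0,0); rows go down
  int col = (int)std::floor((x - ox) / px);
  int row = (int)std::floor((oy - y) / px);
  if (row < 0 || col < 0 || row >= grid.nrow() || col >= grid.ncol()) return 0;
  return grid(row, col) != 0 ? 1 : 0;
}

// reflect radial overshoot at the nucleus edge, iteratively
static inline void reflect(double &x, double &y, double radius) {
  for (int it = 0; it < 20; ++it) {
    double r = std::sqrt(x * x + y * y);
    if (r <= radius || r == 0.0) return;
    double rnew = 2.0 * radius - r;
    if (rnew < 0) rnew = -rnew;           // pathological overshoot beyond 2R
    if (rnew > radius) rnew = radius;     // guard: clamp after repeated folds
    x *= rnew / r;
    y *= rnew / r;
  }
}

// localization noise: bivariate Gaussian truncated at vector norm 3*sigma
static inline void loc_noise(double sigma, double &nx, double &ny) {
  if (sigma <= 0) { nx = 0; ny = 0; return; }
  double lim2 = 9.0 * sigma * sigma;
  for (int it = 0; it < 100; ++it) {
    nx = R::norm_rand() * sigma;
    ny = R::norm_rand() * sigma;
    if (nx * nx + ny * ny <= lim2) return;
  }
  nx = 0; ny = 0;
}

// [[Rcpp::export(name = ".simulate_cell_cpp")]]
List simulate_cell_cpp(IntegerVector start_frame, IntegerVector life_frames,
                       int n_frames, double dt,
                       NumericVector D_free_region, // length 2: euchromatin, heterochromatin
                       double D_bound,
                       NumericVector k_on_region,   // length 2
                       NumericVector f_long_region, // length 2
                       double k_off_short, double k_off_long,
                       double sigma, bool slow_mode, double blur_threshold,
                       double radius,
                       Nullable<IntegerMatrix> chrom_grid,
                       double px_size, double origin_x, double origin_y,
                       bool subframe_switching) {
  int n_mol = start_frame.size();
  bool has_map = chrom_grid.isNotNull();
  IntegerMatrix grid = has_map ? IntegerMatrix(chrom_grid) : IntegerMatrix(1, 1);
  double tau_s = (k_off_short > 0) ? 1.0 / k_off_short : R_PosInf;
  double tau_l = (k_off_long > 0) ? 1.0 / k_off_long : R_PosInf;

  // per molecule-frame output
  std::vector<int> o_mol, o_frame, o_state;
  std::vector<double> o_tx, o_ty, o_ox, o_oy;
  std::vector<int> o_det;
  // bound-event output (continuous times)
  std::vector<int> e_mol, e_state, e_cens_start, e_cens_end;
  std::vector<double> e_t0, e_t1;

  for (int m = 0; m < n_mol; ++m) {
    int a = start_frame[m];
    int end = a + life_frames[m] - 1;
    if (end > n_frames - 1) end = n_frames - 1;
    if (a > end || a >= n_frames) continue;

    // initial position uniform in the disc
    double x, y;
    do {
      x = (2.0 * R::unif_rand() - 1.0) * radius;
      y = (2.0 * R::unif_rand() - 1.0) * radius;
    } while (x * x + y * y > radius * radius);

    // initial state from the local stationary distribution
    int reg = region_at(x, y, grid, px_size, origin_x, origin_y, has_map);
    double kon = k_on_region[reg], fl = f_long_region[reg];
    double Etb = fl * tau_l + (1.0 - fl) * tau_s;
    double Floc = (kon <= 0) ? 0.0 : kon * Etb / (1.0 + kon * Etb);
    int state;
    bool ev_open = false; int ev_state = ST_FREE; double ev_t0 = 0;
    bool ev_cs = false;
    if (R::unif_rand() < Floc) {
      // P(long | bound) weighted by occupancy, not by event frequency
      double p_long_occ = fl * tau_l / Etb;
      state = (R::unif_rand() < p_long_occ) ? ST_LONG : ST_SHORT;
      ev_open = true; ev_state = state; ev_t0 = a * dt; ev_cs = true;
    } else {
      state = ST_FREE;
    }

    for (int f = a; f <= end; ++f) {
      // evolve over the exposure window [f, f+1)*dt with exact exponential
      // switching; states are memoryless so waiting times are resampled
      double trem = dt;
      double t_in[3] = {0, 0, 0};
      reg = region_at(x, y, grid, px_size, origin_x, origin_y, has_map);
      kon = k_on_region[reg]; fl = f_long_region[reg];
      double D_free = D_free_region[reg];
      int state_at_start = state;
      while (true) {
        double rate = (state == ST_FREE) ? kon
                      : (state == ST_SHORT ? k_off_short : k_off_long);
        double w = (rate <= 0) ? R_PosInf : R::exp_rand() / rate;
        if (w >= trem) { t_in[state] += trem; break; }
        t_in[state] += w;
        trem -= w;
        double t_abs = (f + 1) * dt - trem;
        if (state == ST_FREE) {
          state = (R::unif_rand() < fl) ? ST_LONG : ST_SHORT;
          ev_open = true; ev_state = state; ev_t0 = t_abs; ev_cs = false;
        } else {
          if (ev_open) {
            e_mol.push_back(m + 1); e_state.push_back(ev_state);
            e_t0.push_back(ev_t0); e_t1.push_back(t_abs);
            e_cens_start.push_back(ev_cs ? 1 : 0); e_cens_end.push_back(0);
            ev_open = false;
          }
          state = ST_FREE;
        }
      }

      // dominant state within the exposure window
      int dom = 0;
      if (t_in[1] > t_in[dom]) dom = 1;
      if (t_in[2] > t_in[dom]) dom = 2;

      double D_eff;
      if (subframe_switching) {
        D_eff = (t_in[ST_FREE] * D_free + (t_in[ST_SHORT] + t_in[ST_LONG]) * D_bound) / dt;
      } else {
        D_eff = (state_at_start == ST_FREE) ? D_free : D_bound;
      }
      double sd = std::sqrt(2.0 * D_eff * dt);
      double nx0 = x, ny0 = y;
      double xn = x + R::norm_rand() * sd;
      double yn = y + R::norm_rand() * sd;
      reflect(xn, yn, radius);
      double step = std::sqrt((xn - nx0) * (xn - nx0) + (yn - ny0) * (yn - ny0));

      double ex, ey;
      loc_noise(sigma, ex, ey);
      // slow-dwell detectability: the within-exposure motion-blur scale
      // sqrt(2 D_eff t_exp) must stay below the blur threshold; a
      // molecule that spent even a few percent of the exposure free has
      // smeared its emission over several hundred nm (regardless of its
      // net displacement) and is lost in the background, while a
      // molecule bound throughout the frame is always recorded
      bool detected = !slow_mode || (sd <= blur_threshold);

      o_mol.push_back(m + 1);
      o_frame.push_back(f);
      o_state.push_back(dom);
      o_tx.push_back(x); o_ty.push_back(y);
      o_ox.push_back(x + ex); o_oy.push_back(y + ey);
      o_det.push_back(detected ? 1 : 0);

      x = xn; y = yn;
    }
    if (ev_open) { // censored by bleaching / end of acquisition
      e_mol.push_back(m + 1); e_state.push_back(ev_state);
      e_t0.push_back(ev_t0); e_t1.push_back((end + 1) * dt);
      e_cens_start.push_back(ev_cs ? 1 : 0); e_cens_end.push_back(1);
    }
  }

  return List::create(
    _["molecule_id"] = wrap(o_mol), _["frame"] = wrap(o_frame),
    _["state"] = wrap(o_state),
    _["true_x_um"] = wrap(o_tx), _["true_y_um"] = wrap(o_ty),
    _["obs_x_um"] = wrap(o_ox), _["obs_y_um"] = wrap(o_oy),
    _["detected"] = wrap(o_det),
    _["ev_molecule_id"] = wrap(e_mol), _["ev_state"] = wrap(e_state),
    _["ev_t_on"] = wrap(e_t0), _["ev_t_off"] = wrap(e_t1),
    _["ev_censored_start"] = wrap(e_cens_start),
    _["ev_censored_end"] = wrap(e_cens_end));
}
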