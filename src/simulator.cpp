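// Compiled core of the 1D PhuZ spindle simulator.
//
// Two filaments nucleate at the cell poles (x = 0 and x = L) and obey
// dynamic instability: during growth the tip drifts at v_poly - v_depoly
// toward midcell; after a Gaussian-sampled growth interval a catastrophe
// adds a fast depolymerization speed v_cat until a Gaussian-sampled
// recovery time. A growing tip that would cross the near face of the
// nucleus transfers its overshoot to the nucleus unless the opposite tip
// is in contact with the far face, in which case everything jams. The
// nucleus additionally diffuses, clamped at filament contacts and the
// cell boundary.
//
// Each run draws from three independent RNG streams (left filament,
// right filament, nucleus diffusion) derived from (master seed, run
// index, stream id) with splitmix64, so per-run results are stable when
// the number of runs changes and a mirrored run can be produced by
// swapping the filament streams and negating the diffusion stream.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t stream_seed(uint64_t master, uint64_t run, uint64_t stream) {
  uint64_t s = splitmix64(master);
  s = splitmix64(s ^ (run * 0xA24BAED4963EE407ULL));
  s = splitmix64(s ^ (stream * 0x9FB21C651E98DF25ULL));
  return s;
}

//' @name run_child_seed
//' @noRd
// [[Rcpp::export(rng = false)]]
double run_child_seed_cpp(double master, double run, double stream) {
  uint64_t s = stream_seed((uint64_t)master, (uint64_t)run, (uint64_t)stream);
  // reduced to a positive 31-bit integer usable with set.seed()
  return (double)(s % 2147483647ULL) + 1.0;
}

// One collision-resolved displacement update. All positions are measured
// from the left pole in micrometres; dL/dR are the signed tip
// displacements for this step (left tip grows in +x, right tip grows in
// -x so its signed displacement is negative while growing); ddiff is the
// signed diffusion displacement of the nucleus centre.
static inline void resolve_step(double &tipL, double &tipR, double &c,
                                double dL, double dR, double ddiff,
                                double r, double L) {
  double tl = tipL + dL;
  if (tl < 0.0) tl = 0.0;       // a filament never retracts past its origin
  double tr = tipR + dR;
  if (tr > L) tr = L;
  bool pushL = tl > c - r;
  bool pushR = tr < c + r;
  if (pushL && pushR) {
    // two-sided jam: tips advance to contact, nucleus does not move
    tipL = c - r;
    tipR = c + r;
  } else if (pushL) {
    double cn = c + (tl - (c - r));     // overshoot transferred to nucleus
    if (cn > tr - r) cn = tr - r;       // stopped by the opposite tip
    if (cn > L - r) cn = L - r;         // stopped by the cell boundary
    c = cn;
    tipL = std::min(tl, c - r);
    tipR = tr;
  } else if (pushR) {
    double cn = c - ((c + r) - tr);
    if (cn < tl + r) cn = tl + r;
    if (cn < r) cn = r;
    c = cn;
    tipR = std::max(tr, c + r);
    tipL = tl;
  } else {
    tipL = tl;
    tipR = tr;
  }
  // diffusion, clamped at filament contacts and the cell boundary; when
  // both tips are in contact the admissible interval is a point and the
  // nucleus cannot move
  double lo = std::max(r, tipL + r);
  double hi = std::min(L - r, tipR - r);
  double cd = c + ddiff;
  if (cd < lo) cd = lo;
  if (cd > hi) cd = hi;
  c = cd;
}

//' @noRd
// [[Rcpp::export(rng = false)]]
NumericVector resolve_step_cpp(double tip_left, double tip_right, double center,
                               double d_left, double d_right, double d_diff,
                               double radius, double length) {
  resolve_step(tip_left, tip_right, center, d_left, d_right, d_diff,
               radius, length);
  return NumericVector::create(_["tip_left"] = tip_left,
                               _["tip_right"] = tip_right,
                               _["center"] = center);
}

struct Filament {
  double tip;
  int phase;  // 0 = growing, 1 = catastrophe
  double v_poly, v_depoly, v_cat;
  double next_change;
  double next_resample;
};

struct Kin {
  double vp_m, vp_sd, vd_m, vd_sd, vc_m, vc_sd, tc_m, tc_sd, tr_m, tr_sd;
};

// speeds are Gaussian draws clamped at zero from below
static inline double draw_speed(std::mt19937_64 &g,
                                std::normal_distribution<double> &nd,
                                double m, double sd) {
  double x = m + sd * nd(g);
  return x < 0.0 ? 0.0 : x;
}

// interval draws are clamped at zero and floored at dt
static inline double draw_time(std::mt19937_64 &g,
                               std::normal_distribution<double> &nd,
                               double m, double sd, double dt) {
  double x = m + sd * nd(g);
  if (x < 0.0) x = 0.0;
  return x < dt ? dt : x;
}

static inline void resample_speeds(Filament &f, std::mt19937_64 &g,
                                   std::normal_distribution<double> &nd,
                                   const Kin &k) {
  f.v_poly = draw_speed(g, nd, k.vp_m, k.vp_sd);
  f.v_depoly = draw_speed(g, nd, k.vd_m, k.vd_sd);
  f.v_cat = draw_speed(g, nd, k.vc_m, k.vc_sd);
}

//' @noRd
// [[Rcpp::export(rng = false)]]
List simulate_run_cpp(double cell_length, double radius, double diffusion,
                      double init_frac, double dt, double duration,
                      NumericVector kinetics,
                      double master_seed, double run_index,
                      int record_stride, double resample_interval,
                      bool mirror) {
  const double L = cell_length, r = radius;
  Kin k;
  k.vp_m = kinetics["v_poly_mean"];    k.vp_sd = kinetics["v_poly_sd"];
  k.vd_m = kinetics["v_depoly_mean"];  k.vd_sd = kinetics["v_depoly_sd"];
  k.vc_m = kinetics["v_cat_mean"];     k.vc_sd = kinetics["v_cat_sd"];
  k.tc_m = kinetics["t_cat_mean"];     k.tc_sd = kinetics["t_cat_sd"];
  k.tr_m = kinetics["t_rec_mean"];     k.tr_sd = kinetics["t_rec_sd"];

  const uint64_t ms = (uint64_t)master_seed, ri = (uint64_t)run_index;
  std::mt19937_64 genL(stream_seed(ms, ri, mirror ? 2 : 1));
  std::mt19937_64 genR(stream_seed(ms, ri, mirror ? 1 : 2));
  std::mt19937_64 genD(stream_seed(ms, ri, 3));
  std::normal_distribution<double> ndL(0.0, 1.0), ndR(0.0, 1.0), ndD(0.0, 1.0);

  double frac = mirror ? 1.0 - init_frac : init_frac;
  double c = frac * L;
  if (c < r) c = r;
  if (c > L - r) c = L - r;

  Filament fl, fr;
  fl.tip = 0.0; fl.phase = 0;
  fr.tip = L;   fr.phase = 0;
  resample_speeds(fl, genL, ndL, k);
  resample_speeds(fr, genR, ndR, k);
  fl.next_change = draw_time(genL, ndL, k.tc_m, k.tc_sd, dt);
  fr.next_change = draw_time(genR, ndR, k.tc_m, k.tc_sd, dt);
  bool do_resample = std::isfinite(resample_interval) && resample_interval > 0.0;
  fl.next_resample = do_resample ? resample_interval : R_PosInf;
  fr.next_resample = fl.next_resample;

  const long nsteps = (long)std::llround(duration / dt);
  const double sigma = std::sqrt(2.0 * diffusion * dt);

  NumericMatrix traj;
  if (record_stride > 0) {
    // initial state + every stride-th step + the final step if off-stride
    long nrec = 1 + nsteps / record_stride;
    if (nsteps > 0 && (nsteps % record_stride) != 0) ++nrec;
    traj = NumericMatrix(nrec, 6);
  }
  long irec = 0;
  if (record_stride > 0) {
    traj(irec, 0) = 0.0; traj(irec, 1) = fl.tip; traj(irec, 2) = fr.tip;
    traj(irec, 3) = c;   traj(irec, 4) = fl.phase; traj(irec, 5) = fr.phase;
    ++irec;
  }

  for (long i = 0; i < nsteps; ++i) {
    double t = i * dt;
    // phase bookkeeping, each filament on its own stream
    if (t >= fl.next_change) {
      if (fl.phase == 0) {
        fl.phase = 1;
        fl.next_change = t + draw_time(genL, ndL, k.tr_m, k.tr_sd, dt);
      } else {
        fl.phase = 0;
        resample_speeds(fl, genL, ndL, k);
        fl.next_change = t + draw_time(genL, ndL, k.tc_m, k.tc_sd, dt);
      }
    }
    if (t >= fr.next_change) {
      if (fr.phase == 0) {
        fr.phase = 1;
        fr.next_change = t + draw_time(genR, ndR, k.tr_m, k.tr_sd, dt);
      } else {
        fr.phase = 0;
        resample_speeds(fr, genR, ndR, k);
        fr.next_change = t + draw_time(genR, ndR, k.tc_m, k.tc_sd, dt);
      }
    }
    if (do_resample) {
      if (t >= fl.next_resample) {
        resample_speeds(fl, genL, ndL, k);
        fl.next_resample += resample_interval;
      }
      if (t >= fr.next_resample) {
        resample_speeds(fr, genR, ndR, k);
        fr.next_resample += resample_interval;
      }
    }

    double dL = (fl.v_poly - fl.v_depoly - (fl.phase == 1 ? fl.v_cat : 0.0)) * dt;
    double dR = -(fr.v_poly - fr.v_depoly - (fr.phase == 1 ? fr.v_cat : 0.0)) * dt;
    double xi = ndD(genD);
    if (mirror) xi = -xi;
    resolve_step(fl.tip, fr.tip, c, dL, dR, sigma * xi, r, L);

    if (record_stride > 0 && (((i + 1) % record_stride) == 0 || i == nsteps - 1)) {
      traj(irec, 0) = (i + 1) * dt;
      traj(irec, 1) = fl.tip; traj(irec, 2) = fr.tip;
      traj(irec, 3) = c;      traj(irec, 4) = fl.phase; traj(irec, 5) = fr.phase;
      ++irec;
    }
  }

  List out = List::create(
    _["t"] = nsteps * dt,
    _["tip_left"] = fl.tip,
    _["tip_right"] = fr.tip,
    _["nucleus_center"] = c,
    _["phase_left"] = fl.phase,
    _["phase_right"] = fr.phase);
  if (record_stride > 0) {
    colnames(traj) = CharacterVector::create("t_s", "left_tip_um", "right_tip_um",
                                             "nucleus_center_um", "left_phase",
                                             "right_phase");
    out["trajectory"] = traj(Range(0, irec - 1), _);
  }
  return out;
}
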