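// Stochastic motor-clutch engine.
//
// One "end" couples three elements through a shared force balance:
//   * N_c molecular clutches (Hookean springs, stiffness k_c) that bind at
//     constant rate r_on and unbind by Bell's law with a dissociation time
//     constant drawn per binding event from a power law (glassy mode) or
//     fixed at tau_min (conventional mode);
//   * a standard-linear-solid substrate element (k_a, k_l, eta) carrying the
//     summed clutch force F_s = k_c * sum(x_c,i - x_s);
//   * a myosin ensemble with Hill load-velocity relation driving retrograde
//     flow V_r that advects bound clutches.
// The substrate ODE
//   (k_a + k_l) eta dx_s/dt + k_a k_l x_s = k_a F_s + eta dF_s/dt
// is integrated semi-implicitly (backward Euler in x_s) with the clutch
// coupling F_s(x_s) resolved inside the linear solve, so the update is
// unconditionally stable for the linear part.
//
// Clutch extensions e_i = x_c,i - x_s are the stored state; binding occurs
// at zero extension and unbound clutches track the substrate (e_i = 0), so
// F_s = k_c * sum over bound clutches of e_i at all times.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <climits>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64: fast, seedable, and independent of
// R's RNG so whole-cell runs are bit-reproducible from an integer seed.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  Xoshiro(uint64_t seed, uint64_t stream) {
    // distinct streams: perturb the seed by the stream index before mixing
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL * (stream + 1ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif_co() {            // [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double unif_oc() {            // (0, 1]
    return ((next() >> 11) + 1ULL) * (1.0 / 9007199254740992.0);
  }
};

// --------------------------------------------------------------- model ----

struct Params {
  int n_clutches;
  double k_c, r_on, f_bond;
  int n_motors;
  double f_motor, v_u;
  double k_a, k_l, eta;
  bool glassy;
  bool per_episode;
  double beta, tau_min, tau_max;
  double dt;
  double body_drag;
  bool center_velocity;
  // precomputed
  double f_stall, p_on, inv_bm1;
  double A, B, E;                      // substrate solve coefficients

  explicit Params(const List &p) {
    n_clutches = as<int>(p["n_clutches"]);
    k_c = as<double>(p["k_c"]);
    r_on = as<double>(p["r_on"]);
    f_bond = as<double>(p["f_bond"]);
    n_motors = as<int>(p["n_motors"]);
    f_motor = as<double>(p["f_motor"]);
    v_u = as<double>(p["v_u"]);
    k_a = as<double>(p["k_a"]);
    k_l = as<double>(p["k_l"]);
    eta = as<double>(p["eta"]);
    glassy = as<std::string>(p["off_time_mode"]) == "glassy";
    per_episode = as<std::string>(p["tau_sampling"]) == "per_episode";
    beta = as<double>(p["beta"]);
    tau_min = as<double>(p["tau_min"]);
    tau_max = as<double>(p["tau_max"]);
    dt = as<double>(p["dt"]);
    body_drag = as<double>(p["body_drag"]);
    center_velocity = as<bool>(p["center_velocity"]);

    f_stall = n_motors * f_motor;
    p_on = -std::expm1(-r_on * dt);
    inv_bm1 = glassy ? 1.0 / (beta - 1.0) : 0.0;
    A = (k_a + k_l) * eta / dt;
    B = k_a * k_l;
    E = k_a + eta / dt;
  }

  inline double hill(double f_load) const {
    if (n_motors == 0) return 0.0;
    double v = v_u * (1.0 - f_load / f_stall);
    if (v < 0.0) return 0.0;
    if (v > v_u) return v_u;
    return v;
  }

  inline double draw_tau(Xoshiro &rng) const {
    if (!glassy) return tau_min;
    double tau = tau_min * std::pow(rng.unif_oc(), -inv_bm1);
    if (tau > tau_max) tau = tau_max;  // optional hygiene cap, default +Inf
    return tau;
  }
};

struct End {
  std::vector<uint8_t> bound;
  std::vector<double> ext;             // x_c - x_s, nonzero only when bound
  std::vector<double> tau_off;
  // exact-survival sampling state:
  //  * bound clutches unbind in the step where the accumulated hazard
  //    sum(r_off * dt) first exceeds a pre-drawn Exp(1) budget — identical in
  //    law to per-step Bernoulli(1 - exp(-r_off dt)) draws;
  //  * unbound clutches bind after a geometric number of steps with
  //    p = 1 - exp(-r_on dt).
  std::vector<double> hazard;          // accumulated sum of r_off * dt
  std::vector<double> budget;          // Exp(1) survival budget
  std::vector<long> bind_in;           // steps until binding
  double x_s, f_s, v_r;
  double max_residual;                 // force-bookkeeping check
  // cluster-level off-time state (tau_sampling = "per_episode"): the
  // adhesion cluster of an end occupies one glassy configuration at a time,
  // characterized by a shared dissociation time constant tau; the
  // configuration itself renews at rate 1/tau (trap-model dynamics), so
  // deep (large-tau) states persist long but never forever and each
  // migration step samples the off-time law afresh
  double shared_tau;
  long renew_in;                       // steps until configuration renewal
  int n_bound_live;

  explicit End(int n)
      : bound(n, 0), ext(n, 0.0), tau_off(n, 0.0),
        hazard(n, 0.0), budget(n, 0.0), bind_in(n, 0),
        x_s(0.0), f_s(0.0), v_r(0.0), max_residual(0.0),
        shared_tau(1.0), renew_in(LONG_MAX), n_bound_live(0) {}
};

// geometric (>= 1) number of steps until an unbound clutch binds
static inline long draw_bind_in(const Params &P, Xoshiro &rng) {
  if (P.p_on <= 0.0) return LONG_MAX;
  if (P.p_on >= 1.0) return 1;
  return 1 + (long)std::floor(std::log(rng.unif_oc()) /
                              std::log1p(-P.p_on));
}

// exponential lifetime (mean tau) of the current glassy configuration
static inline long draw_renew_in(const Params &P, double tau, Xoshiro &rng) {
  double t = -std::log(rng.unif_oc()) * tau / P.dt;
  if (t < 1.0) return 1;
  if (t > 9e18) return LONG_MAX;
  return (long)t;
}

static inline void init_end(End &e, const Params &P, Xoshiro &rng) {
  for (int i = 0; i < P.n_clutches; ++i) e.bind_in[i] = draw_bind_in(P, rng);
  if (P.per_episode) {
    e.shared_tau = P.draw_tau(rng);
    e.renew_in = draw_renew_in(P, e.shared_tau, rng);
  }
}

// cluster-configuration renewal, once per end per timestep
static inline void renew_cluster_tau(End &e, const Params &P, Xoshiro &rng) {
  if (P.per_episode && --e.renew_in <= 0) {
    e.shared_tau = P.draw_tau(rng);
    e.renew_in = draw_renew_in(P, e.shared_tau, rng);
  }
}

// one timestep of a single end; returns the retrograde flow used this step
static inline double end_step(End &e, const Params &P, Xoshiro &rng) {
  const int n = P.n_clutches;
  // (1) motor load and retrograde flow from the current transmitted force
  const double f_load = e.f_s > 0.0 ? e.f_s : 0.0;
  const double v_r = P.hill(f_load);
  e.v_r = v_r;

  // (2) advect bound clutches with the actin flow
  const double adv = v_r * P.dt;
  double S = 0.0;                      // sum of bound extensions
  int nb = 0;
  for (int i = 0; i < n; ++i) {
    if (e.bound[i]) {
      e.ext[i] += adv;
      S += e.ext[i];
      ++nb;
    }
  }

  // (3) substrate update, clutch coupling resolved in the solve:
  //     F_s' = k_c*S - nb*k_c*(x_s' - x_s)
  const double G = P.k_c * S;
  const double H = nb * P.k_c;
  const double x_new = (P.A * e.x_s + P.E * (G + H * e.x_s) -
                        (P.eta / P.dt) * e.f_s) /
                       (P.A + P.B + P.E * H);
  const double delta = x_new - e.x_s;
  e.x_s = x_new;
  const double f_pred = G - H * delta;
  double S2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (e.bound[i]) {
      e.ext[i] -= delta;
      S2 += e.ext[i];
    }
  }
  double f_new = P.k_c * S2;
  {
    double r = std::fabs(f_new - f_pred);
    if (r > e.max_residual) e.max_residual = r;
  }

  // (4) Monte Carlo clutch kinetics: exact exponential survival, at most one
  //     transition per clutch per step; binding at zero extension with a
  //     fresh dissociation time constant
  renew_cluster_tau(e, P, rng);
  double S3 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!e.bound[i]) {
      if (--e.bind_in[i] <= 0) {
        e.bound[i] = 1;
        e.ext[i] = 0.0;
        e.tau_off[i] = P.per_episode ? e.shared_tau : P.draw_tau(rng);
        ++e.n_bound_live;
        e.hazard[i] = 0.0;
        e.budget[i] = -std::log(rng.unif_oc());   // Exp(1)
      }
    } else {
      if (e.ext[i] < 0.0) e.ext[i] = 0.0;   // slack tether buckles: no
                                            // compressive force, no Bell
                                            // amplification
      const double fc = P.k_c * e.ext[i];
      e.hazard[i] += std::exp(fc / P.f_bond) / e.tau_off[i] * P.dt;
      if (e.hazard[i] >= e.budget[i]) {
        e.bound[i] = 0;
        e.ext[i] = 0.0;              // unbound clutches carry no force
        --e.n_bound_live;
        e.bind_in[i] = draw_bind_in(P, rng);
      } else {
        S3 += e.ext[i];
      }
    }
  }
  // (5) re-establish F_s = k_c * sum of bound extensions
  e.f_s = P.k_c * S3;
  return v_r;
}

// ---------------------------------------------------- coupled axis step ---
//
// Whole-cell force balance: the two ends of an axis are linked through the
// cell body, so their transmitted forces are equal and opposite at all
// times (quasi-static equilibrium at the cell center). Per step the cell
// velocity V is solved so that the semi-implicitly updated end tensions
// match: each end's post-step tension is affine in its stretch-input
// velocity w (w_L = V_r,L + V, w_R = V_r,R - V), giving a closed-form V.
// Measured relative to the substrate the end flows are V_r,L + V and
// V_r,R - V, so V is half the difference of the substrate-frame retrograde
// flows. |V| is capped at V_u, the speed of the actin machinery itself
// (regularizes the instant a fully detached end carries no tension).

struct AffineResp {
  double a, b;                         // T' = a + b * w
  double S0;                           // current sum of bound extensions
  int nb;
};

static inline AffineResp force_response(End &e, const Params &P) {
  AffineResp r;
  r.S0 = 0.0;
  r.nb = 0;
  const int n = P.n_clutches;
  for (int i = 0; i < n; ++i) {
    if (e.bound[i]) {
      r.S0 += e.ext[i];
      ++r.nb;
    }
  }
  const double H = r.nb * P.k_c;
  const double denom = P.A + P.B + P.E * H;
  r.b = (P.A + P.B) * P.k_c * r.nb * P.dt / denom;
  r.a = ((P.A + P.B) * P.k_c * r.S0 +
         H * (P.B * e.x_s + (P.eta / P.dt) * e.f_s)) / denom;
  return r;
}

// advance one end given its stretch-input velocity w; mirrors end_step
// phases (2)-(5) with advection w*dt instead of V_r*dt
static inline void end_substep(End &e, const Params &P, double w,
                               Xoshiro &rng) {
  const int n = P.n_clutches;
  const double adv = w * P.dt;
  double S = 0.0;
  int nb = 0;
  for (int i = 0; i < n; ++i) {
    if (e.bound[i]) {
      e.ext[i] += adv;
      S += e.ext[i];
      ++nb;
    }
  }
  const double G = P.k_c * S;
  const double H = nb * P.k_c;
  const double x_new = (P.A * e.x_s + P.E * (G + H * e.x_s) -
                        (P.eta / P.dt) * e.f_s) /
                       (P.A + P.B + P.E * H);
  const double delta = x_new - e.x_s;
  e.x_s = x_new;
  const double f_pred = G - H * delta;
  double S2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (e.bound[i]) {
      e.ext[i] -= delta;
      S2 += e.ext[i];
    }
  }
  {
    double r = std::fabs(P.k_c * S2 - f_pred);
    if (r > e.max_residual) e.max_residual = r;
  }
  renew_cluster_tau(e, P, rng);
  double S3 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!e.bound[i]) {
      if (--e.bind_in[i] <= 0) {
        e.bound[i] = 1;
        e.ext[i] = 0.0;
        e.tau_off[i] = P.per_episode ? e.shared_tau : P.draw_tau(rng);
        ++e.n_bound_live;
        e.hazard[i] = 0.0;
        e.budget[i] = -std::log(rng.unif_oc());
      }
    } else {
      if (e.ext[i] < 0.0) e.ext[i] = 0.0;   // slack tether buckles: no
                                            // compressive force, no Bell
                                            // amplification
      const double fc = P.k_c * e.ext[i];
      e.hazard[i] += std::exp(fc / P.f_bond) / e.tau_off[i] * P.dt;
      if (e.hazard[i] >= e.budget[i]) {
        e.bound[i] = 0;
        e.ext[i] = 0.0;
        --e.n_bound_live;
        e.bind_in[i] = draw_bind_in(P, rng);
      } else {
        S3 += e.ext[i];
      }
    }
  }
  e.f_s = P.k_c * S3;
}

// one timestep of a two-ended axis with center force balance; returns the
// cell velocity V (positive toward the "right" end)
static inline double axis_step_center(End &L, End &R, const Params &P,
                                      Xoshiro &rng) {
  const double vrL = P.hill(L.f_s > 0.0 ? L.f_s : 0.0);
  const double vrR = P.hill(R.f_s > 0.0 ? R.f_s : 0.0);
  L.v_r = vrL;
  R.v_r = vrR;
  const AffineResp rL = force_response(L, P);
  const AffineResp rR = force_response(R, P);
  // body equilibrium with a small viscous drag zeta on the cell body:
  // T_R' - T_L' = zeta * V, so an adhesion-free cell generates no motion
  double V = 0.0;
  const double denom = P.body_drag + rL.b + rR.b;
  if (denom > 0.0) {
    V = ((rR.a + rR.b * vrR) - (rL.a + rL.b * vrL)) / denom;
    if (V > P.v_u) V = P.v_u;
    if (V < -P.v_u) V = -P.v_u;
  }
  end_substep(L, P, vrL + V, rng);
  end_substep(R, P, vrR - V, rng);
  return V;
}

// one timestep with independent (per-end) force balance: each end's motor
// load is its own clutch force, migration from the retrograde-flow
// difference (optionally halved for the cell center)
static inline double axis_step_per_end(End &L, End &R, const Params &P,
                                       Xoshiro &rng) {
  const double vL = end_step(L, P, rng);
  const double vR = end_step(R, P, rng);
  return (P.center_velocity ? 0.5 : 1.0) * (vL - vR);
}

// ------------------------------------------------------------- drivers ----

// Whole-cell trajectory: per axis two opposing ends coupled through the
// cell-center force balance (default) or run independently (per-end mode).
// [[Rcpp::export]]
List cpp_simulate_cell(List params, double seed, double stream,
                       int dimensions, double duration,
                       double record_interval, double burn_in,
                       bool center_balance, bool diagnostics) {
  Params P(params);
  Xoshiro rng((uint64_t)seed, (uint64_t)stream);

  const int rec_every = std::max(1, (int)std::lround(record_interval / P.dt));
  const int n_frames = (int)std::floor(duration / (rec_every * P.dt));
  const long n_steps = (long)n_frames * rec_every;

  std::vector<End> ends;
  ends.reserve(2 * dimensions);
  for (int k = 0; k < 2 * dimensions; ++k) {
    ends.emplace_back(P.n_clutches);
    init_end(ends.back(), P, rng);
  }

  NumericVector times(n_frames + 1);
  NumericMatrix pos(n_frames + 1, dimensions);
  // optional per-frame end-state traces (first axis only)
  NumericMatrix diag(diagnostics ? n_frames + 1 : 0, 6);
  double cur[2] = {0.0, 0.0};
  times[0] = 0.0;

  // equilibration: run the clutch/motor/substrate state past the artificial
  // all-unbound start before recording
  const long n_burn = (long)std::floor(burn_in / P.dt);
  for (long step = 0; step < n_burn; ++step) {
    for (int ax = 0; ax < dimensions; ++ax) {
      if (center_balance) {
        axis_step_center(ends[2 * ax], ends[2 * ax + 1], P, rng);
      } else {
        axis_step_per_end(ends[2 * ax], ends[2 * ax + 1], P, rng);
      }
    }
  }

  int frame = 0;
  for (long step = 1; step <= n_steps; ++step) {
    for (int ax = 0; ax < dimensions; ++ax) {
      const double vm = center_balance
        ? axis_step_center(ends[2 * ax], ends[2 * ax + 1], P, rng)
        : axis_step_per_end(ends[2 * ax], ends[2 * ax + 1], P, rng);
      cur[ax] += vm * P.dt;
    }
    if (step % rec_every == 0) {
      ++frame;
      times[frame] = frame * rec_every * P.dt;
      for (int ax = 0; ax < dimensions; ++ax) {
        pos(frame, ax) = cur[ax];
        if (!std::isfinite(cur[ax])) {
          stop("integration failure: non-finite position at step %d", (int)step);
        }
      }
      if (diagnostics) {
        const End &L = ends[0], &R = ends[1];
        int nbL = 0, nbR = 0;
        for (int i = 0; i < P.n_clutches; ++i) {
          nbL += L.bound[i];
          nbR += R.bound[i];
        }
        diag(frame, 0) = L.f_s;
        diag(frame, 1) = R.f_s;
        diag(frame, 2) = L.v_r;
        diag(frame, 3) = R.v_r;
        diag(frame, 4) = nbL;
        diag(frame, 5) = nbR;
      }
    }
  }

  double resid = 0.0;
  for (size_t k = 0; k < ends.size(); ++k) {
    if (ends[k].max_residual > resid) resid = ends[k].max_residual;
  }

  return List::create(_["times"] = times, _["pos"] = pos,
                      _["force_residual"] = resid,
                      _["diag"] = diag);
}

// Single-end diagnostic trace: transmitted force, retrograde flow, bound
// count and substrate displacement, recorded every `record_every` steps.
// [[Rcpp::export]]
List cpp_simulate_end(List params, double seed, double stream,
                      double duration, int record_every) {
  Params P(params);
  Xoshiro rng((uint64_t)seed, (uint64_t)stream);
  End e(P.n_clutches);
  init_end(e, P, rng);

  const long n_steps = (long)std::floor(duration / P.dt);
  const long n_rec = n_steps / record_every;
  NumericVector times(n_rec), f_s(n_rec), v_r(n_rec), x_s(n_rec);
  IntegerVector n_bound(n_rec);

  long r = 0;
  for (long step = 1; step <= n_steps; ++step) {
    end_step(e, P, rng);
    if (step % record_every == 0 && r < n_rec) {
      times[r] = step * P.dt;
      f_s[r] = e.f_s;
      v_r[r] = e.v_r;
      x_s[r] = e.x_s;
      int nb = 0;
      for (int i = 0; i < P.n_clutches; ++i) nb += e.bound[i];
      n_bound[r] = nb;
      if (!std::isfinite(e.f_s) || !std::isfinite(e.x_s)) {
        stop("integration failure: non-finite end state at step %d", (int)step);
      }
      ++r;
    }
  }
  return List::create(_["times"] = times, _["f_s"] = f_s, _["v_r"] = v_r,
                      _["x_s"] = x_s, _["n_bound"] = n_bound,
                      _["force_residual"] = e.max_residual);
}
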