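// Exact stochastic simulation (Gillespie direct method) of the digitalizer
// reaction network at system size omega (molecules per nM). Propensities are
// the ODE fluxes evaluated at concentrations x = n/omega and multiplied by
// omega, so the ODE is recovered in the omega -> Inf limit. Hill terms are
// used as-is at the count level (no elementary operator-binding reactions).
//
// Per-cell streams are derived from (seed, cell_index) with a splitmix64
// counter hash, so populations are reproducible and order-independent.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double alpha_R, beta_R, K_TF, n_act, alpha_S, K_R, n_rep, k_pair;
  double delta_mR, delta_mS, delta_R, delta_G, lambda_R, lambda_G, mu;
};

Pars unpack(const NumericVector& p) {
  Pars q;
  q.alpha_R = p["alpha_R"]; q.beta_R = p["beta_R"]; q.K_TF = p["K_TF"];
  q.n_act = p["n_act"]; q.alpha_S = p["alpha_S"]; q.K_R = p["K_R"];
  q.n_rep = p["n_rep"]; q.k_pair = p["k_pair"]; q.delta_mR = p["delta_mR"];
  q.delta_mS = p["delta_mS"]; q.delta_R = p["delta_R"]; q.delta_G = p["delta_G"];
  q.lambda_R = p["lambda_R"]; q.lambda_G = p["lambda_G"]; q.mu = p["mu"];
  return q;
}

inline double hill_act(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x / K, n);
  return xn / (1.0 + xn);
}

// splitmix64: mixes (seed, cell_index) into a well-spread 64-bit stream seed
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed, uint64_t cell) {
    s = splitmix64(splitmix64(seed) ^ splitmix64(cell * 0x9e3779b97f4a7c15ULL + 1ULL));
    if (s == 0) s = 0x106689d45497fdb5ULL;
  }
  inline uint64_t next() {  // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545f4914f6cdd1dULL;
  }
  inline double unif() {  // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double exp1() { return -std::log(unif()); }
};

constexpr int N_REACT = 9;
// stoichiometry over (mR, mS, R, G)
const int STOICH[N_REACT][4] = {
  {+1, 0, 0, 0},   // P1 transcription
  {0, +1, 0, 0},   // P2 transcription
  {-1, 0, 0, 0},   // mR decay (+ dilution)
  {0, -1, 0, 0},   // mS decay (+ dilution)
  {-1, -1, 0, 0},  // pairing co-degradation
  {0, 0, +1, 0},   // R translation
  {0, 0, 0, +1},   // G translation
  {0, 0, -1, 0},   // R decay (+ dilution)
  {0, 0, 0, -1}    // G decay (+ dilution)
};

inline void propensities(const Pars& q, double omega, const double* n,
                         double p1_rate, double* a) {
  a[0] = omega * p1_rate;
  a[1] = omega * q.alpha_S * (1.0 - hill_act(n[2] / omega, q.K_R, q.n_rep));
  a[2] = (q.delta_mR + q.mu) * n[0];
  a[3] = (q.delta_mS + q.mu) * n[1];
  a[4] = (q.k_pair / omega) * n[0] * n[1];
  a[5] = q.lambda_R * n[0];
  a[6] = q.lambda_G * n[0];
  a[7] = (q.delta_R + q.mu) * n[2];
  a[8] = (q.delta_G + q.mu) * n[3];
}

}  // namespace

// Simulate one cell; returns states at snapshot times plus life status.
// If record_all, also returns the full event trajectory (capped at max_records).
// toxin_threshold > 0 enables one-hit death: the cell dies the moment G
// reaches the threshold and its state freezes at the death time.
// [[Rcpp::export(name = ".ssa_cell")]]
List ssa_cell(NumericVector params, double omega,
              NumericVector breakpoints, NumericVector levels,
              NumericVector snapshot_times, NumericVector init_counts,
              double seed, double cell_index,
              double toxin_threshold = 0.0, bool record_all = false,
              double max_records = 2e6) {
  Pars q = unpack(params);
  if (omega <= 0) stop("omega must be > 0");
  Rng rng(static_cast<uint64_t>(seed), static_cast<uint64_t>(cell_index));

  double n[4];
  for (int i = 0; i < 4; ++i) {
    n[i] = std::floor(init_counts[i] + 0.5);
    if (n[i] < 0) stop("initial counts must be non-negative");
  }

  const int n_snap = snapshot_times.size();
  NumericMatrix snap(n_snap, 4);
  int next_snap = 0;

  const int n_seg = breakpoints.size();
  if (n_seg < 1 || levels.size() != n_seg) stop("invalid protocol");
  double t = breakpoints[0];
  double t_end = snapshot_times[n_snap - 1];
  int seg = 0;

  std::vector<double> rec_t, rec_s;
  if (record_all) { rec_t.reserve(1024); rec_s.reserve(4096); }
  auto record = [&](double tt) {
    if (!record_all) return;
    if (rec_t.size() >= static_cast<size_t>(max_records))
      stop("trajectory exceeds max_records; raise max_records or disable record_all");
    rec_t.push_back(tt);
    for (int i = 0; i < 4; ++i) rec_s.push_back(n[i]);
  };

  bool alive = true;
  double death_time = NA_REAL;
  auto flush_snaps = [&](double upto) {
    while (next_snap < n_snap && snapshot_times[next_snap] <= upto + 1e-12) {
      for (int i = 0; i < 4; ++i) snap(next_snap, i) = n[i];
      ++next_snap;
    }
  };

  record(t);
  if (toxin_threshold > 0 && n[3] >= toxin_threshold) { alive = false; death_time = t; }

  double a[N_REACT];
  while (alive && t < t_end) {
    while (seg + 1 < n_seg && breakpoints[seg + 1] <= t) ++seg;
    double seg_end = (seg + 1 < n_seg) ? breakpoints[seg + 1] : t_end;
    if (seg_end > t_end) seg_end = t_end;
    double p1_rate = q.beta_R + q.alpha_R * hill_act(levels[seg], q.K_TF, q.n_act);

    propensities(q, omega, n, p1_rate, a);
    double a0 = 0.0;
    for (int i = 0; i < N_REACT; ++i) a0 += a[i];
    if (!std::isfinite(a0)) stop("propensity overflow");

    double t_next;
    if (a0 <= 0.0) {
      t_next = seg_end;  // nothing can fire; jump to the next protocol segment
    } else {
      t_next = t + rng.exp1() / a0;
    }
    if (t_next >= seg_end) {
      // waiting time crosses a protocol breakpoint (or the horizon):
      // advance and redraw with the new propensities (memorylessness)
      flush_snaps(seg_end);
      t = seg_end;
      if (seg_end >= t_end) break;
      continue;
    }
    flush_snaps(t_next);
    t = t_next;
    double r = rng.unif() * a0;
    int j = 0;
    double acc = a[0];
    while (j < N_REACT - 1 && r > acc) acc += a[++j];
    for (int i = 0; i < 4; ++i) n[i] += STOICH[j][i];
    record(t);
    if (toxin_threshold > 0 && n[3] >= toxin_threshold) {
      alive = false;
      death_time = t;
    }
  }
  // state is constant (or frozen at death) through any remaining snapshots
  flush_snaps(t_end);
  while (next_snap < n_snap) {
    for (int i = 0; i < 4; ++i) snap(next_snap, i) = n[i];
    ++next_snap;
  }

  List out = List::create(_["snapshots"] = snap, _["alive"] = alive,
                          _["death_time"] = death_time);
  if (record_all) {
    int m = rec_t.size();
    NumericMatrix traj(m, 5);
    for (int i = 0; i < m; ++i) {
      traj(i, 0) = rec_t[i];
      for (int k = 0; k < 4; ++k) traj(i, k + 1) = rec_s[4 * i + k];
    }
    colnames(traj) = CharacterVector::create("time", "mR", "mS", "R", "G");
    out["trajectory"] = traj;
  }
  return out;
}

// Population of independent cells; returns per-cell states at each snapshot
// time, stacked as an (n_cells * n_snap) x 6 matrix:
// (cell, time, mR, mS, R, G) plus an alive flag vector per cell.
// [[Rcpp::export(name = ".ssa_population")]]
List ssa_population(NumericVector params, double omega,
                    NumericVector breakpoints, NumericVector levels,
                    NumericVector snapshot_times, NumericVector init_counts,
                    double seed, double n_cells, double toxin_threshold = 0.0) {
  const int nc = static_cast<int>(n_cells);
  const int ns = snapshot_times.size();
  NumericMatrix out(nc * ns, 6);
  LogicalVector alive(nc);
  NumericVector death(nc);
  for (int c = 0; c < nc; ++c) {
    List one = ssa_cell(params, omega, breakpoints, levels, snapshot_times,
                        init_counts, seed, c + 1, toxin_threshold, false, 0);
    NumericMatrix snap = one["snapshots"];
    alive[c] = as<bool>(one["alive"]);
    death[c] = as<double>(one["death_time"]);
    for (int s = 0; s < ns; ++s) {
      int row = c * ns + s;
      out(row, 0) = c + 1;
      out(row, 1) = snapshot_times[s];
      for (int k = 0; k < 4; ++k) out(row, k + 2) = snap(s, k);
    }
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("cell", "time", "mR", "mS", "R", "G");
  return List::create(_["states"] = out, _["alive"] = alive,
                      _["death_time"] = death);
}
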