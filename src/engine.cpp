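// Serial trial engine. One trial: place a clone group on distinct start
// slots, then for T timesteps iterate the animats in a per-trial random
// serial order: sense the live occupancy -> update the Markov brain via a
// precomputed full-state lookup table -> apply the motor action. Gate
// crossings (room-label changes through a gate cell) and co-occupancy
// collisions are logged and scored.
//
// All randomness comes from a std::mt19937 seeded per trial; bounded draws
// use modulo reduction so that a given seed reproduces the trial exactly.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_build_state_table(List gates, int n_units, int n_sensors) {
  const int n_states = 1 << n_units;
  IntegerVector out(n_states);
  const int n_gates = gates.size();
  std::vector<std::vector<int>> G(n_gates);
  for (int g = 0; g < n_gates; ++g) {
    G[g] = as<std::vector<int>>(gates[g]);
  }
  for (int s = 0; s < n_states; ++s) {
    int nxt = 0;
    for (int g = 0; g < n_gates; ++g) {
      const std::vector<int>& v = G[g];
      const int n_in = v[0], n_out = v[1];
      int idx = 0;
      for (int i = 0; i < n_in; ++i) {
        idx |= ((s >> v[2 + i]) & 1) << i;
      }
      const int val = v[2 + n_in + n_out + idx];
      for (int j = 0; j < n_out; ++j) {
        if ((val >> j) & 1) nxt |= 1 << v[2 + n_in + j];
      }
    }
    out[s] = nxt;
  }
  return out;
}

namespace {

struct TrialResult {
  std::vector<double> score;
  std::vector<int> n_rewarded;
  std::vector<double> n_coll;
  // log (filled only when full_log)
  std::vector<int> t, animat, x, y, dir, sensors, state, action;
  std::vector<int> crossing, rewarding, collided;
};

inline void side_delta(int dir, int side, int& dx, int& dy) {
  // dir: 0 up, 1 right, 2 down, 3 left; side: 0 front, 1 left, 2 right
  int d = dir;
  if (side == 1) d = (dir + 3) % 4;
  if (side == 2) d = (dir + 1) % 4;
  switch (d) {
    case 0: dx = 0; dy = -1; break;
    case 1: dx = 1; dy = 0; break;
    case 2: dx = 0; dy = 1; break;
    default: dx = -1; dy = 0; break;
  }
}

TrialResult run_trial_core(const IntegerMatrix& cell, const IntegerMatrix& room,
                           const IntegerMatrix& reward_cell,
                           const IntegerMatrix& slots, const IntegerVector& table,
                           int n_units, int n_sensors,
                           const IntegerVector& sensor_kind,
                           const IntegerVector& sensor_side,
                           int group_size, int T,
                           bool penalty_active, double penalty, bool blocking,
                           double reward, int refractory, int reward_cap,
                           unsigned int seed, bool full_log) {
  const int height = cell.nrow(), width = cell.ncol();
  const int n_slots = slots.nrow();
  std::mt19937 rng(seed);

  // start slots sampled without replacement (partial Fisher-Yates)
  std::vector<int> idx(n_slots);
  for (int i = 0; i < n_slots; ++i) idx[i] = i;
  for (int i = 0; i < group_size; ++i) {
    int j = i + rng() % (n_slots - i);
    std::swap(idx[i], idx[j]);
  }

  std::vector<int> x(group_size), y(group_size), dir(group_size), mm(group_size, 0);
  std::vector<int> last_room(group_size), last_gate_rw(group_size, 0);
  std::vector<int> last_cross(group_size, -1000000), n_rewarded(group_size, 0);
  std::vector<double> n_coll(group_size, 0.0);
  std::vector<int> occ(height * width, 0);

  for (int a = 0; a < group_size; ++a) {
    x[a] = slots(idx[a], 0);
    y[a] = slots(idx[a], 1);
    dir[a] = rng() % 4;
    last_room[a] = room(y[a], x[a]);
    occ[y[a] * width + x[a]] += 1;
  }

  // serial order: one permutation per trial, reused every timestep
  std::vector<int> order(group_size);
  for (int i = 0; i < group_size; ++i) order[i] = i;
  for (int i = group_size - 1; i > 0; --i) {
    int j = rng() % (i + 1);
    std::swap(order[i], order[j]);
  }

  TrialResult res;
  res.n_rewarded.assign(group_size, 0);
  res.n_coll.assign(group_size, 0.0);
  if (full_log) {
    const size_t n = (size_t)T * group_size;
    res.t.resize(n); res.animat.resize(n); res.x.resize(n); res.y.resize(n);
    res.dir.resize(n); res.sensors.resize(n); res.state.resize(n);
    res.action.resize(n); res.crossing.assign(n, 0);
    res.rewarding.assign(n, NA_INTEGER); res.collided.assign(n, 0);
  }

  const int motor_l = n_units - 2, motor_r = n_units - 1;

  for (int t = 1; t <= T; ++t) {
    for (int k = 0; k < group_size; ++k) {
      const int a = order[k];
      // sense the single adjacent cell on each sensor's side
      int sbits = 0;
      for (int s = 0; s < n_sensors; ++s) {
        int dx, dy;
        side_delta(dir[a], sensor_side[s], dx, dy);
        const int cx = x[a] + dx, cy = y[a] + dy;
        bool wall = cx < 0 || cx >= width || cy < 0 || cy >= height ||
                    cell(cy, cx) == 1;
        bool agent = !wall && occ[cy * width + cx] > 0;
        bool fire = false;
        switch (sensor_kind[s]) {
          case 0: fire = wall; break;
          case 1: fire = agent; break;
          default: fire = wall || agent; break;
        }
        if (fire) sbits |= 1 << s;
      }
      const int full = sbits | mm[a];
      const int newmm = table[full];
      mm[a] = newmm;
      const int ml = (newmm >> motor_l) & 1, mr = (newmm >> motor_r) & 1;
      int action = 0;  // 0 none, 1 turn left, 2 turn right, 3 forward
      int crossing = 0, rewarding = NA_INTEGER;
      if (ml == 1 && mr == 1) {
        int dx, dy;
        side_delta(dir[a], 0, dx, dy);
        const int tx = x[a] + dx, ty = y[a] + dy;
        bool ok = !(tx < 0 || tx >= width || ty < 0 || ty >= height ||
                    cell(ty, tx) == 1);
        if (ok && blocking && occ[ty * width + tx] > 0) ok = false;
        if (ok) {
          action = 3;
          occ[y[a] * width + x[a]] -= 1;
          x[a] = tx; y[a] = ty;
          occ[ty * width + tx] += 1;
          if (cell(ty, tx) == 2) {
            last_gate_rw[a] = reward_cell(ty, tx);
          } else {
            const int r = room(ty, tx);
            if (r != last_room[a]) {
              crossing = 1;
              rewarding = last_gate_rw[a];
              const bool spaced = (t - last_cross[a]) > refractory;
              if (rewarding == 1 && spaced && n_rewarded[a] < reward_cap) {
                n_rewarded[a] += 1;
              }
              last_cross[a] = t;
              last_room[a] = r;
            }
          }
        }
      } else if (ml == 1) {
        action = 1;
        dir[a] = (dir[a] + 3) % 4;
      } else if (mr == 1) {
        action = 2;
        dir[a] = (dir[a] + 1) % 4;
      }
      if (full_log) {
        const size_t r = (size_t)(t - 1) * group_size + a;
        res.t[r] = t; res.animat[r] = a + 1;
        res.x[r] = x[a]; res.y[r] = y[a]; res.dir[r] = dir[a];
        res.sensors[r] = sbits; res.state[r] = sbits | newmm;
        res.action[r] = action; res.crossing[r] = crossing;
        res.rewarding[r] = rewarding;
      }
    }
    // collision accounting: every animat on a cell with occupancy > 1
    for (int a = 0; a < group_size; ++a) {
      if (occ[y[a] * width + x[a]] > 1) {
        n_coll[a] += 1.0;
        if (full_log) res.collided[(size_t)(t - 1) * group_size + a] = 1;
      }
    }
  }

  res.score.resize(group_size);
  for (int a = 0; a < group_size; ++a) {
    res.score[a] = reward * n_rewarded[a] -
      (penalty_active ? penalty * n_coll[a] : 0.0);
    res.n_rewarded[a] = n_rewarded[a];
    res.n_coll[a] = n_coll[a];
  }
  return res;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_trial(IntegerMatrix cell, IntegerMatrix room,
                   IntegerMatrix reward_cell, IntegerMatrix slots,
                   IntegerVector table, int n_units, int n_sensors,
                   IntegerVector sensor_kind, IntegerVector sensor_side,
                   int group_size, int T,
                   bool penalty_active, double penalty, bool blocking,
                   double reward, int refractory, int reward_cap,
                   int seed, bool full_log) {
  TrialResult r = run_trial_core(cell, room, reward_cell, slots, table,
                                 n_units, n_sensors, sensor_kind, sensor_side,
                                 group_size, T, penalty_active, penalty,
                                 blocking, reward, refractory, reward_cap,
                                 (unsigned int)seed, full_log);
  List out = List::create(
    _["score"] = wrap(r.score),
    _["n_rewarded"] = wrap(r.n_rewarded),
    _["n_collisions"] = wrap(r.n_coll));
  if (full_log) {
    out["log"] = DataFrame::create(
      _["t"] = wrap(r.t), _["animat"] = wrap(r.animat),
      _["x"] = wrap(r.x), _["y"] = wrap(r.y),
      _["orientation"] = wrap(r.dir), _["sensor_state"] = wrap(r.sensors),
      _["state"] = wrap(r.state), _["action"] = wrap(r.action),
      _["crossing"] = wrap(r.crossing), _["gate_rewarding"] = wrap(r.rewarding),
      _["collided"] = wrap(r.collided));
  }
  return out;
}

// one score per trial: the score of one uniformly chosen animat
// [[Rcpp::export]]
NumericVector cpp_score_trials(IntegerMatrix cell, IntegerMatrix room,
                               IntegerMatrix reward_cell, IntegerMatrix slots,
                               IntegerVector table, int n_units, int n_sensors,
                               IntegerVector sensor_kind, IntegerVector sensor_side,
                               IntegerVector group_sizes, int T,
                               bool penalty_active, double penalty, bool blocking,
                               double reward, int refractory, int reward_cap,
                               IntegerVector seeds) {
  const int n_trials = seeds.size();
  NumericVector out(n_trials);
  for (int j = 0; j < n_trials; ++j) {
    const int gs = group_sizes[j % group_sizes.size()];
    TrialResult r = run_trial_core(cell, room, reward_cell, slots, table,
                                   n_units, n_sensors, sensor_kind, sensor_side,
                                   gs, T, penalty_active, penalty, blocking,
                                   reward, refractory, reward_cap,
                                   (unsigned int)seeds[j], false);
    std::mt19937 pick_rng((unsigned int)seeds[j] ^ 0x9e3779b9u);
    out[j] = r.score[pick_rng() % gs];
  }
  return out;
}
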