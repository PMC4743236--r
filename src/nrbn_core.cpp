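#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Synchronous-update engine shared by attractor search, trajectories and
// the flip/relaxation protocol. States are vectors of 0/1 bytes; a state's
// hash key is its raw byte string, whose lexicographic order coincides with
// the integer encoding that takes the first node as the most significant
// bit (the same convention used for truth-table rows).

namespace {

struct Net {
  int n;
  std::vector< std::vector<int> > reg;   // 0-based regulator indices
  std::vector< std::vector<int> > tab;   // truth table, first regulator = MSB
  std::vector<int> clamp;                // -1 free, 0/1 forced
};

Net make_net(const List& reg, const List& tab, const IntegerVector& clamp) {
  Net net;
  net.n = reg.size();
  net.reg.resize(net.n);
  net.tab.resize(net.n);
  net.clamp.assign(clamp.begin(), clamp.end());
  for (int i = 0; i < net.n; ++i) {
    IntegerVector r = reg[i];
    IntegerVector t = tab[i];
    net.reg[i].assign(r.begin(), r.end());
    net.tab[i].assign(t.begin(), t.end());
  }
  return net;
}

typedef std::vector<uint8_t> State;

inline void step_state(const Net& net, const State& s, State& out) {
  for (int i = 0; i < net.n; ++i) {
    if (net.clamp[i] >= 0) { out[i] = (uint8_t) net.clamp[i]; continue; }
    const std::vector<int>& r = net.reg[i];
    size_t idx = 0;
    for (size_t j = 0; j < r.size(); ++j) idx = (idx << 1) | s[r[j]];
    out[i] = (uint8_t) net.tab[i][idx];
  }
}

inline std::string key_of(const State& s) {
  return std::string(s.begin(), s.end());
}

int canonical_start(const std::vector<State>& cyc) {
  int best = 0;
  for (size_t i = 1; i < cyc.size(); ++i)
    if (cyc[i] < cyc[best]) best = (int) i;
  return best;
}

IntegerMatrix cycle_to_matrix(const std::vector<State>& cyc, int start) {
  int L = (int) cyc.size(), n = (int) cyc[0].size();
  IntegerMatrix m(L, n);
  for (int i = 0; i < L; ++i) {
    const State& s = cyc[(start + i) % L];
    for (int j = 0; j < n; ++j) m(i, j) = s[j];
  }
  return m;
}

void decode_code(double code, int n, State& s) {
  // node 0 is the most significant bit
  for (int j = 0; j < n; ++j) {
    double w = std::ldexp(1.0, n - 1 - j);
    if (code >= w) { s[j] = 1; code -= w; } else s[j] = 0;
  }
}

} // namespace

// Attractor search from a set of initial states (or the full state space).
// `known` seeds the attractor registry so relaxations can be mapped onto an
// existing atlas; new cycles are appended in discovery order. Trajectories
// that do not close within max_steps updates are unresolved (NA).
// [[Rcpp::export]]
List C_attractor_search(List reg, List tab, IntegerVector clamp,
                        IntegerMatrix inits, bool exhaustive,
                        int max_steps, List known, double memo_limit) {
  Net net = make_net(reg, tab, clamp);
  const int n = net.n;

  std::unordered_map<std::string, int> state2attr;  // 0-based ids
  std::vector< std::vector<State> > cycles;

  for (int a = 0; a < known.size(); ++a) {
    IntegerMatrix m = known[a];
    std::vector<State> cyc((size_t) m.nrow(), State(n));
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < n; ++j) cyc[i][j] = (uint8_t) m(i, j);
    int id = (int) cycles.size();
    for (size_t i = 0; i < cyc.size(); ++i) state2attr[key_of(cyc[i])] = id;
    cycles.push_back(cyc);
  }

  R_xlen_t n_init;
  if (exhaustive) {
    if (n > 28) stop("exhaustive search limited to 28 nodes internally");
    n_init = (R_xlen_t) 1 << n;
  } else {
    n_init = inits.nrow();
  }

  IntegerVector assign(n_init, NA_INTEGER);
  State cur(n), nxt(n);
  std::vector<State> path;
  std::unordered_map<std::string, int> local;

  for (R_xlen_t ii = 0; ii < n_init; ++ii) {
    if (exhaustive) decode_code((double) ii, n, cur);
    else for (int j = 0; j < n; ++j) cur[j] = (uint8_t) inits(ii, j);

    path.clear();
    local.clear();
    int dest = -1;

    for (int t = 0; t <= max_steps; ++t) {
      std::string key = key_of(cur);
      std::unordered_map<std::string, int>::iterator g = state2attr.find(key);
      if (g != state2attr.end()) { dest = g->second; break; }
      std::unordered_map<std::string, int>::iterator l = local.find(key);
      if (l != local.end()) {
        // closed a new cycle: states path[l->second .. end]
        std::vector<State> cyc(path.begin() + l->second, path.end());
        int start = canonical_start(cyc);
        std::vector<State> canon(cyc.size());
        for (size_t i = 0; i < cyc.size(); ++i)
          canon[i] = cyc[(start + i) % cyc.size()];
        int id = (int) cycles.size();
        for (size_t i = 0; i < canon.size(); ++i)
          state2attr[key_of(canon[i])] = id;
        cycles.push_back(canon);
        dest = id;
        break;
      }
      if (t == max_steps) break;  // budget exhausted without closing
      local[key] = (int) path.size();
      path.push_back(cur);
      step_state(net, cur, nxt);
      cur.swap(nxt);
    }

    if (dest >= 0) {
      assign[ii] = dest + 1;
      if ((double) state2attr.size() < memo_limit)
        for (size_t i = 0; i < path.size(); ++i) {
          std::string key = key_of(path[i]);
          if (state2attr.find(key) == state2attr.end()) state2attr[key] = dest;
        }
    }
    if ((ii & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }

  List attractors((int) cycles.size());
  IntegerVector lengths((int) cycles.size());
  for (size_t a = 0; a < cycles.size(); ++a) {
    int start = canonical_start(cycles[a]);
    attractors[(int) a] = cycle_to_matrix(cycles[a], start);
    lengths[(int) a] = (int) cycles[a].size();
  }
  return List::create(_["assign"] = assign,
                      _["attractors"] = attractors,
                      _["lengths"] = lengths);
}

// Iterate the synchronous map from s0, stopping when a previously visited
// state recurs or max_steps updates have been applied. Returns the distinct
// visited states, whether the orbit closed, and the (1-based) index of the
// state the orbit re-entered.
// [[Rcpp::export]]
List C_trajectory(List reg, List tab, IntegerVector clamp,
                  IntegerVector s0, int max_steps) {
  Net net = make_net(reg, tab, clamp);
  const int n = net.n;
  State cur(n), nxt(n);
  for (int j = 0; j < n; ++j) cur[j] = (uint8_t) s0[j];

  std::vector<State> path;
  std::unordered_map<std::string, int> seen;
  bool closed = false;
  int entry = NA_INTEGER;

  for (int t = 0; t <= max_steps; ++t) {
    std::string key = key_of(cur);
    std::unordered_map<std::string, int>::iterator it = seen.find(key);
    if (it != seen.end()) { closed = true; entry = it->second + 1; break; }
    if (t == max_steps) break;
    seen[key] = (int) path.size();
    path.push_back(cur);
    step_state(net, cur, nxt);
    cur.swap(nxt);
  }

  IntegerMatrix m((int) path.size(), n);
  for (size_t i = 0; i < path.size(); ++i)
    for (int j = 0; j < n; ++j) m((int) i, j) = path[i][j];
  return List::create(_["states"] = m, _["closed"] = closed,
                      _["entry"] = entry);
}

// Apply n_steps synchronous updates to each row of `states`.
// [[Rcpp::export]]
IntegerMatrix C_step_many(List reg, List tab, IntegerVector clamp,
                          IntegerMatrix states, int n_steps) {
  Net net = make_net(reg, tab, clamp);
  const int n = net.n;
  IntegerMatrix out(states.nrow(), n);
  State cur(n), nxt(n);
  for (int i = 0; i < states.nrow(); ++i) {
    for (int j = 0; j < n; ++j) cur[j] = (uint8_t) states(i, j);
    for (int t = 0; t < n_steps; ++t) {
      step_state(net, cur, nxt);
      cur.swap(nxt);
    }
    for (int j = 0; j < n; ++j) out(i, j) = cur[j];
  }
  return out;
}
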