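// SimPol: stochastic simulation of RNA polymerase movement along a gene in a
// population of cells. Discrete time slices (default 1e-4 min); in each
// slice a polymerase at site i advances one nucleotide with probability
// p_move[i] = zeta_bar * zeta_i * dt unless another polymerase blocks its
// path, and a new polymerase initiates at site 1 with probability
// alpha * dt when the first `footprint` sites are free. Blocking uses the
// start-of-slice positions. Occupancy is the time-and-cell-averaged
// indicator of active-site presence over a measurement window (by default
// the second half of the simulated time).
//
// Two samplers are provided. The slice sampler iterates literally over time
// slices. The event sampler exploits the memorylessness of the per-slice
// Bernoulli trials: the departure slice of a polymerase from site i is
//   dep(i) = max(entry(i), dep_leader(i + footprint)) + Geometric(p_move[i])
// and initiations follow the same rule with p_init, which reproduces the
// slice process exactly while drawing one geometric variate per site visit.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, deterministic across platforms
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

const double INF_SLICE = 1e18;

}  // namespace

// [[Rcpp::export]]
NumericVector simpol_event_cpp(NumericVector p_move, double p_init,
                               int n_cells, int footprint,
                               double win_start, double win_end,
                               double seed) {
  const int N = p_move.size();
  // geometric wait at site i: 1 + floor(log(U) / log(1 - p)); p >= 1 gives a
  // deterministic wait of one slice, p <= 0 never moves
  std::vector<double> inv_log1mp(N);
  std::vector<char> never(N, 0);
  for (int i = 0; i < N; ++i) {
    if (p_move[i] >= 1.0) inv_log1mp[i] = 0.0;
    else if (p_move[i] <= 0.0) { never[i] = 1; inv_log1mp[i] = 0.0; }
    else inv_log1mp[i] = 1.0 / std::log1p(-p_move[i]);
  }
  const bool init_never = (p_init <= 0.0);
  const double init_log = (p_init >= 1.0 || init_never) ? 0.0
    : 1.0 / std::log1p(-p_init);
  std::vector<double> occ(N, 0.0), dep(N);
  for (int cell = 0; cell < n_cells; ++cell) {
    Rng rng((uint64_t)seed * 2654435761ULL + 0x1234ULL + (uint64_t)cell);
    std::fill(dep.begin(), dep.end(), 0.0);
    double last_init_gate = 0.0;  // dep of previous polymerase from site `footprint`
    while (true) {
      if (init_never) break;  // alpha == 0: no initiations
      double wait = (init_log == 0.0) ? 1.0
        : 1.0 + std::floor(std::log(rng.unif()) * init_log);
      double t = last_init_gate + wait;  // slice at which the polymerase appears
      if (t > win_end) break;
      double cur = t;  // entry slice into current site
      for (int i = 0; i < N; ++i) {
        double gate = cur;
        int ahead = i + footprint;
        if (ahead < N && dep[ahead] > gate) gate = dep[ahead];
        double d;
        if (never[i]) d = INF_SLICE;
        else if (inv_log1mp[i] == 0.0) d = gate + 1.0;
        else d = gate + 1.0 + std::floor(std::log(rng.unif()) * inv_log1mp[i]);
        // occupies site i during slices [cur, d - 1]
        double lo = cur > win_start ? cur : win_start;
        double hi = (d - 1.0) < win_end ? (d - 1.0) : win_end;
        if (hi >= lo) occ[i] += hi - lo + 1.0;
        dep[i] = d;
        if (i + 1 == footprint) last_init_gate = d;
        cur = d;
        if (cur > win_end) {
          // later sites are reached outside the window; the stale dep[]
          // entries ahead only constrain polymerases that are themselves
          // already past the window, so they cannot affect measured occupancy
          break;
        }
      }
      if (footprint > N) last_init_gate = cur;  // degenerate, gene shorter than footprint
    }
  }
  const double denom = (double)n_cells * (win_end - win_start + 1.0);
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = occ[i] / denom;
  return out;
}

// [[Rcpp::export]]
NumericVector simpol_slice_cpp(NumericVector p_move, double p_init,
                               int n_cells, int footprint,
                               double win_start, double win_end,
                               double seed) {
  const int N = p_move.size();
  std::vector<double> occ(N, 0.0);
  const long T = (long)win_end;
  for (int cell = 0; cell < n_cells; ++cell) {
    Rng rng((uint64_t)seed * 2654435761ULL + 0x9876ULL + (uint64_t)cell);
    std::vector<int> pos;  // active sites, front polymerase first (0-based)
    for (long t = 1; t <= T; ++t) {
      const size_t np = pos.size();
      // decide moves from start-of-slice positions
      std::vector<bool> mv(np, false);
      for (size_t k = 0; k < np; ++k) {
        int i = pos[k];
        bool blocked = (k > 0) && (pos[k - 1] <= i + footprint);
        if (!blocked && rng.unif() < p_move[i]) mv[k] = true;
      }
      bool init_free = pos.empty() || pos.back() >= footprint;
      bool do_init = init_free && rng.unif() < p_init;
      for (size_t k = 0; k < np; ++k) if (mv[k]) ++pos[k];
      // polymerases leaving the gene
      while (!pos.empty() && pos.front() >= N) pos.erase(pos.begin());
      if (do_init) pos.push_back(0);
      if (t >= (long)win_start)
        for (size_t k = 0; k < pos.size(); ++k) occ[pos[k]] += 1.0;
    }
  }
  const double denom = (double)n_cells * (win_end - win_start + 1.0);
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = occ[i] / denom;
  return out;
}
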