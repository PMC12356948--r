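#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Counter-free 64-bit RNG: splitmix64 used to expand a seed into xoshiro256**
// state; xoshiro256** drives all simulation randomness.  Self-contained so
// trajectories are bit-reproducible across platforms for a given seed.
namespace tanarng {

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

} // namespace tanarng

// Derive a 64-bit stream seed from a master seed and a stream index.
// [[Rcpp::export(name = ".cpp_derive_seed")]]
double cpp_derive_seed(double master_seed, double stream) {
  uint64_t x = (uint64_t)master_seed ^ ((uint64_t)stream << 32);
  uint64_t z = tanarng::splitmix64(x);
  // return as double below 2^53 so R can hold it exactly
  return (double)(z >> 11);
}

// Sample a Tangled Nature interaction matrix.
// Off-diagonal entry (i,j) is present with probability theta and then
// Uniform(-1,1); diagonal is 0.  pairwise = one coin per unordered pair
// (both directed entries present or absent together, values independent).
// neutral = every permitted entry replaced by the constant neutral_weight.
// [[Rcpp::export(name = ".cpp_sample_interactions")]]
NumericMatrix cpp_sample_interactions(int M, double theta, double seed,
                                      bool pairwise, bool neutral,
                                      double neutral_weight) {
  tanarng::Xoshiro rng((uint64_t)seed);
  NumericMatrix J(M, M);
  if (!pairwise) {
    for (int i = 0; i < M; ++i) {
      for (int j = 0; j < M; ++j) {
        if (i == j) continue;
        if (rng.unif() < theta) {
          double w = neutral ? neutral_weight : (2.0 * rng.unif() - 1.0);
          J(i, j) = w;
        }
      }
    }
  } else {
    for (int i = 0; i < M; ++i) {
      for (int j = i + 1; j < M; ++j) {
        if (rng.unif() < theta) {
          double wij = neutral ? neutral_weight : (2.0 * rng.unif() - 1.0);
          double wji = neutral ? neutral_weight : (2.0 * rng.unif() - 1.0);
          J(i, j) = wij;
          J(j, i) = wji;
        }
      }
    }
  }
  return J;
}

namespace {

struct EcoState {
  int M;
  // occupied species kept in parallel arrays for linear scans
  std::vector<int> occ;     // occupied species ids (unsorted)
  std::vector<int> cnt;     // counts, aligned with occ
  std::vector<int> pos;     // index into occ, -1 if absent
  long long N;

  explicit EcoState(int M_) : M(M_), pos(M_, -1), N(0) {}

  inline void add(int sp) {
    int idx = pos[sp];
    if (idx < 0) {
      pos[sp] = (int)occ.size();
      occ.push_back(sp);
      cnt.push_back(1);
    } else {
      ++cnt[idx];
    }
    ++N;
  }
  inline void removeAt(int idx) {
    if (--cnt[idx] == 0) {
      int sp = occ[idx];
      occ[idx] = occ.back();
      cnt[idx] = cnt.back();
      pos[occ[idx]] = idx;
      occ.pop_back();
      cnt.pop_back();
      pos[sp] = -1;
    }
    --N;
  }
  // occ-index of the species of the r-th individual, r in [0, N)
  inline int individualIdx(long long r) const {
    long long cum = 0;
    const size_t S = occ.size();
    for (size_t a = 0; a + 1 < S; ++a) {
      cum += cnt[a];
      if (r < cum) return (int)a;
    }
    return (int)S - 1;
  }
};

} // namespace

// One full Tangled Nature run.
//
// Each generation consists of max(1, round(N(t)/p_kill)) timesteps, N(t)
// taken at the generation's start.  A timestep is: (a) with probability
// p_kill remove one uniformly chosen individual; (b) if any individuals
// remain, one uniformly chosen individual reproduces with probability
// 1/(1+exp(-H)) where H = (k/N) sum_j J[s,j] n_j - mu N; each offspring
// genome bit flips independently with probability p_mut.
//
// Returns the sparse per-generation record (species/counts/lengths),
// per-generation totals, and optionally per-timestep totals.
// [[Rcpp::export(name = ".cpp_tana_run")]]
List cpp_tana_run(int L, double theta, double p_kill, double p_mut,
                  double k, double mu, int n0, int n0_species,
                  int n_generations, double seed_run, double seed_J,
                  Nullable<NumericMatrix> J_in,
                  bool pairwise, bool neutral, double neutral_weight,
                  bool replace_parent, bool record_timesteps = false) {
  const int M = 1 << L;
  NumericMatrix J = J_in.isNotNull()
    ? NumericMatrix(J_in)
    : cpp_sample_interactions(M, theta, seed_J, pairwise, neutral,
                              neutral_weight);
  if (J.nrow() != M || J.ncol() != M)
    stop("interaction matrix must be %d x %d", M, M);

  // row-contiguous copy of J so the fitness sum over occupied species
  // walks memory linearly
  std::vector<double> Jrowmaj((size_t)M * M);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < M; ++i)
      Jrowmaj[(size_t)i * M + j] = J(i, j);

  tanarng::Xoshiro rng((uint64_t)seed_run);
  EcoState st(M);

  // initial condition: n0 individuals spread uniformly over n0_species
  // distinct uniformly chosen species
  std::vector<int> init_sp;
  {
    std::vector<char> used(M, 0);
    while ((int)init_sp.size() < n0_species) {
      int sp = (int)(rng.unif() * M);
      if (sp >= M) sp = M - 1;
      if (!used[sp]) { used[sp] = 1; init_sp.push_back(sp); }
    }
    for (int i = 0; i < n0; ++i) {
      int a = (int)(rng.unif() * n0_species);
      if (a >= n0_species) a = n0_species - 1;
      st.add(init_sp[a]);
    }
  }

  std::vector<int> rec_species, rec_counts, rec_len, rec_total;
  std::vector<int> ts_total;
  rec_len.reserve(n_generations);
  rec_total.reserve(n_generations);

  const double pmut_none = std::pow(1.0 - p_mut, L);
  bool extinct = false;
  int gens_done = 0;

  for (int g = 0; g < n_generations && !extinct; ++g) {
    long long T = (long long)std::llround((double)st.N / p_kill);
    if (T < 1) T = 1;
    for (long long t = 0; t < T; ++t) {
      // annihilation
      if (rng.unif() < p_kill) {
        long long r = (long long)(rng.unif() * st.N);
        if (r >= st.N) r = st.N - 1;
        st.removeAt(st.individualIdx(r));
        if (st.N == 0) { extinct = true; if (record_timesteps) ts_total.push_back(0); break; }
      }
      // reproduction
      {
        long long r = (long long)(rng.unif() * st.N);
        if (r >= st.N) r = st.N - 1;
        int s = st.occ[st.individualIdx(r)];
        const double *Jrow = &Jrowmaj[(size_t)s * M];
        double inter = 0.0;
        const double Nd = (double)st.N;
        const size_t S = st.occ.size();
        for (size_t a = 0; a < S; ++a)
          inter += Jrow[st.occ[a]] * st.cnt[a];
        double H = (k / Nd) * inter - mu * Nd;
        double p_off = 1.0 / (1.0 + std::exp(-H));
        if (rng.unif() < p_off) {
          // mutated copy of genome s
          auto offspring = [&]() -> int {
            if (p_mut > 0.0 && rng.unif() >= pmut_none) {
              // at least one bit flips: rejection-sample the flip pattern
              int pattern = 0;
              do {
                pattern = 0;
                for (int b = 0; b < L; ++b)
                  if (rng.unif() < p_mut) pattern |= (1 << b);
              } while (pattern == 0);
              return s ^ pattern;
            }
            return s;
          };
          if (replace_parent) {
            // original-model reproduction: the parent is replaced by two
            // independently mutated copies (net +1 individual)
            st.removeAt(st.pos[s]);
            st.add(offspring());
            st.add(offspring());
          } else {
            // budding variant: parent retained, one mutated offspring added
            st.add(offspring());
          }
        }
      }
      if (record_timesteps) ts_total.push_back((int)st.N);
    }
    if (extinct) break;
    // record generation state (species ids ascending)
    std::vector<int> ids(st.occ.begin(), st.occ.end());
    std::sort(ids.begin(), ids.end());
    for (int sp : ids) {
      rec_species.push_back(sp);
      rec_counts.push_back(st.cnt[st.pos[sp]]);
    }
    rec_len.push_back((int)ids.size());
    rec_total.push_back((int)st.N);
    gens_done = g + 1;
  }

  return List::create(
    _["species"] = wrap(rec_species),
    _["counts"] = wrap(rec_counts),
    _["gen_sizes"] = wrap(rec_len),
    _["totals"] = wrap(rec_total),
    _["n_generations"] = gens_done,
    _["terminated_early"] = extinct,
    _["timestep_totals"] = wrap(ts_total));
}
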