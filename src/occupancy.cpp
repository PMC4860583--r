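#include <Rcpp.h>
#include <cstdint>
#include <vector>

// xoshiro128++ — small fast PRNG, seeded from R's RNG so results follow
// set.seed(); quality is ample for occupancy counting.
static inline uint32_t rotl(const uint32_t x, int k) {
  return (x << k) | (x >> (32 - k));
}

struct Xoshiro128pp {
  uint32_t s[4];
  explicit Xoshiro128pp(uint64_t seed) {
    // splitmix64 expansion of the seed into state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = static_cast<uint32_t>((z ^ (z >> 31)) & 0xffffffffULL);
    }
  }
  inline uint32_t next() {
    const uint32_t result = rotl(s[0] + s[3], 7) + s[0];
    const uint32_t t = s[1] << 9;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 11);
    return result;
  }
  // unbiased uniform integer in [0, n)
  inline uint32_t bounded(uint32_t n) {
    uint32_t x = next();
    uint64_t m = static_cast<uint64_t>(x) * n;
    uint32_t l = static_cast<uint32_t>(m);
    if (l < n) {
      uint32_t t = (-n) % n;
      while (l < t) {
        x = next();
        m = static_cast<uint64_t>(x) * n;
        l = static_cast<uint32_t>(m);
      }
    }
    return static_cast<uint32_t>(m >> 32);
  }
};

// [[Rcpp::export]]
Rcpp::IntegerVector occupancy_mc_cpp(int r, int L, int nrep,
                                     int seed1, int seed2) {
  Xoshiro128pp rng((static_cast<uint64_t>(static_cast<uint32_t>(seed1)) << 32)
                   ^ static_cast<uint32_t>(seed2));
  Rcpp::IntegerVector out(nrep);
  std::vector<uint32_t> stamp(static_cast<size_t>(L), 0u);
  uint32_t epoch = 0u;
  const uint32_t Lu = static_cast<uint32_t>(L);
  for (int rep = 0; rep < nrep; ++rep) {
    ++epoch;
    if (epoch == 0u) {  // stamp wrap-around: reset
      std::fill(stamp.begin(), stamp.end(), 0u);
      epoch = 1u;
    }
    int occ = 0;
    for (int i = 0; i < r; ++i) {
      uint32_t pos = rng.bounded(Lu);
      if (stamp[pos] != epoch) {
        stamp[pos] = epoch;
        ++occ;
      }
    }
    out[rep] = occ;
  }
  return out;
}
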