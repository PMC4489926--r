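#ifndef STICKYKNOTS_RNG_H
#define STICKYKNOTS_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding; self-contained so trajectories are
// bit-reproducible across platforms for a given 64-bit seed.
struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_gauss = false;
    gauss_val = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1); never exactly 0
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }

  bool have_gauss;
  double gauss_val;

  // standard normal, Marsaglia polar method (no trig, deterministic)
  inline double gauss() {
    if (have_gauss) {
      have_gauss = false;
      return gauss_val;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    gauss_val = v * f;
    have_gauss = true;
    return u * f;
  }
};

#endif
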