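#pragma once
#include <cstdint>
#include <cmath>

// xoshiro256** seeded via splitmix64; one instance per run keeps streams
// reproducible and independent of R's global RNG.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  int unif_int(int n) {
    int k = (int)(unif() * n);
    return k < n ? k : n - 1;
  }
  // Marsaglia's method: uniform direction on the unit sphere
  void unit_vector(double* v) {
    double a, b, s2;
    do {
      a = 2.0 * unif() - 1.0;
      b = 2.0 * unif() - 1.0;
      s2 = a * a + b * b;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s2);
    v[0] = a * f; v[1] = b * f; v[2] = 1.0 - 2.0 * s2;
  }
};
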