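#ifndef CORNEACPM_ENGINE_H
#define CORNEACPM_ENGINE_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

// Cell-type codes shared with the R side (see R/types.R).
enum CType {
  T_AIR = 0, T_STEM = 1, T_BASAL = 2, T_WING = 3, T_SUPER = 4,
  T_TEAR = 5, T_LIMB = 6, T_MEMB = 7, T_STROMA = 8, T_WALL = 9, T_DMG = 10
};
static const int NTYPES = 11;

inline bool type_is_epithelial(int t) { return t >= T_STEM && t <= T_SUPER; }
// Frozen compartments never gain or lose pixels through Metropolis dynamics.
inline bool type_is_frozen(int t) { return t >= T_LIMB; }
// Pixels eligible to take part in a pixel-copy attempt (either side).
inline bool type_is_mobile(int t) { return t >= T_STEM && t <= T_TEAR; }
// "Solid" surface for tear-film re-wetting: anything the tear rests upon.
inline bool type_is_solid(int t) {
  return type_is_epithelial(t) || t == T_LIMB || t == T_MEMB ||
         t == T_STROMA || t == T_DMG;
}

// Deterministic RNG: one stream per run segment, seeded from R.
struct RunRNG {
  std::mt19937_64 g;
  explicit RunRNG(uint64_t seed) : g(seed) {}
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(g() % static_cast<uint64_t>(n)); }
};

inline double harmonic_mean_D(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// Operator-split implicit diffusion-decay step (see field.cpp).
void field_substep(std::vector<double>& conc, const std::vector<double>& dmap,
                   const std::vector<unsigned char>& clamp_mask,
                   double clamp_value, double kd, double dt, int W, int H,
                   bool dirichlet_top_bottom);

#endif
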