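#ifndef SPATPHAGE_KINETICS_H
#define SPATPHAGE_KINETICS_H

#include <cmath>
#include <algorithm>

// Colony-protection kinetics shared by the exported R wrappers and the
// stochastic lattice engine. All populations are real-valued here (the engine
// stores integer-valued doubles); rates are per hour.

namespace spatphage {

// Monod saturation factor n / (n + K). K > 0; n < 0 treated as exhausted.
inline double monod(double n, double K) {
  if (n <= 0.0) return 0.0;
  return n / (n + K);
}

// Unclipped shielding S~ = exp(-(1/zeta) * (((B+I)/n_c)^(1/3) - (B/n_c)^(1/3))).
// The exponent is the infected-layer thickness in units of the bacterial
// radius; zeta is the typical phage penetration depth in the same units.
inline double shielding_raw(double B, double I, double n_c, double zeta) {
  if (I <= 0.0) return 1.0;
  double s = std::cbrt((B + I) / n_c) - std::cbrt(B / n_c);
  return std::exp(-s / zeta);
}

// Shielding with the small-colony upper bound: S = min(B/(B+I), S~).
// At B + I = 0 no adsorption can occur; S is defined as 1 to keep the
// function total.
inline double shielding(double B, double I, double n_c, double zeta) {
  double tot = B + I;
  if (tot <= 0.0) return 1.0;
  return std::min(B / tot, shielding_raw(B, I, n_c, zeta));
}

// Free-phage adsorption rate to colonies (events per hour per box):
// eta_box * ((B+I)/n_c)^(1/3) * n_c * P, Smoluchowski target-radius scaling.
// eta_box is the adsorption constant already divided by the box volume.
inline double colony_adsorption_rate(double B, double I, double n_c, double P,
                                     double eta_box) {
  double tot = B + I;
  if (tot <= 0.0 || n_c <= 0.0 || P <= 0.0) return 0.0;
  return eta_box * std::cbrt(tot / n_c) * n_c * P;
}

}  // namespace spatphage

#endif
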