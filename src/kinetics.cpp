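#include <Rcpp.h>
#include "kinetics.h"

using namespace Rcpp;

// Vectorised exports of the kinetics primitives. Argument recycling follows
// the usual R rules for length-1 arguments only; lengths are validated in the
// R wrappers.

// [[Rcpp::export]]
NumericVector cpp_monod(NumericVector n, NumericVector K) {
  R_xlen_t len = std::max(n.size(), K.size());
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i)
    out[i] = spatphage::monod(n[i % n.size()], K[i % K.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_shielding_raw(NumericVector B, NumericVector I,
                                NumericVector n_c, NumericVector zeta) {
  R_xlen_t len = std::max(std::max(B.size(), I.size()),
                          std::max(n_c.size(), zeta.size()));
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    double b = B[i % B.size()], in = I[i % I.size()];
    double nc = n_c[i % n_c.size()], z = zeta[i % zeta.size()];
    if (nc <= 0.0 && b + in > 0.0)
      stop("shielding is undefined for n_c = 0 with B + I > 0");
    out[i] = (b + in <= 0.0) ? 1.0 : spatphage::shielding_raw(b, in, nc, z);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_shielding(NumericVector B, NumericVector I,
                            NumericVector n_c, NumericVector zeta) {
  R_xlen_t len = std::max(std::max(B.size(), I.size()),
                          std::max(n_c.size(), zeta.size()));
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    double b = B[i % B.size()], in = I[i % I.size()];
    double nc = n_c[i % n_c.size()], z = zeta[i % zeta.size()];
    if (nc <= 0.0 && b + in > 0.0)
      stop("shielding is undefined for n_c = 0 with B + I > 0");
    out[i] = spatphage::shielding(b, in, nc, z);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_colony_adsorption_rate(NumericVector B, NumericVector I,
                                         NumericVector n_c, NumericVector P,
                                         NumericVector eta_box) {
  R_xlen_t len = std::max(std::max(B.size(), I.size()),
                          std::max(std::max(n_c.size(), P.size()),
                                   eta_box.size()));
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i)
    out[i] = spatphage::colony_adsorption_rate(
        B[i % B.size()], I[i % I.size()], n_c[i % n_c.size()],
        P[i % P.size()], eta_box[i % eta_box.size()]);
  return out;
}

// Split beta * n_lysed progeny phages into (escaped, readsorbed): each phage
// escapes the colony independently with probability 1 - alpha. Uses the R RNG.
// [[Rcpp::export]]
List cpp_partition_burst(NumericVector n_lysed, double beta, double alpha) {
  R_xlen_t len = n_lysed.size();
  NumericVector escaped(len), readsorbed(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    double total = beta * n_lysed[i];
    double esc;
    if (alpha <= 0.0) esc = total;
    else if (alpha >= 1.0) esc = 0.0;
    else esc = R::rbinom(total, 1.0 - alpha);
    escaped[i] = esc;
    readsorbed[i] = total - esc;
  }
  return List::create(_["escaped"] = escaped, _["readsorbed"] = readsorbed);
}
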