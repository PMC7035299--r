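#include <Rcpp.h>
#include <vector>
#include "kinetics.h"

using namespace Rcpp;

// Stochastic tau-leaping engine over a 3-D lattice of well-mixed boxes.
//
// All population fields are integer-valued doubles (counts can exceed the
// 32-bit integer range in whole-volume boxes); the nutrient field is a
// continuous density in bacteria-equivalents per box. Event counts per box
// per step are drawn from Poisson distributions at start-of-phase rates and
// clamped to the available reactants, in the fixed order
//   growth -> adsorption/infection -> stage advance -> lysis -> decay
// followed by phage hop diffusion and FTCS nutrient diffusion. Draws are
// consumed in a fixed lattice-scan order from R's global RNG, so a seed fixes
// the entire trajectory.

namespace {

struct EngPars {
  int level;          // 1 = no latency stages, 2/3 = free-cell, 4 = colony
  bool singleton;     // level-4 limit check: n_c tracks B + I
  int n_stages;
  double lambda, r, beta, delta, alpha, zeta;
  double K_box, eta_box, dt, p_hop, c_n;
  int nx, ny, nz, N;
  int bc[3];          // 0 periodic, 1 reflective
};

EngPars parse_pars(const List& pars) {
  EngPars g;
  g.level = as<int>(pars["level"]);
  g.singleton = as<bool>(pars["singleton"]);
  g.n_stages = as<int>(pars["n_stages"]);
  g.lambda = as<double>(pars["lambda"]);
  g.r = as<double>(pars["stage_rate"]);
  g.beta = as<double>(pars["beta"]);
  g.delta = as<double>(pars["delta"]);
  g.alpha = as<double>(pars["alpha"]);
  g.zeta = as<double>(pars["zeta"]);
  g.K_box = as<double>(pars["K_box"]);
  g.eta_box = as<double>(pars["eta_box"]);
  g.dt = as<double>(pars["dt"]);
  g.p_hop = as<double>(pars["p_hop"]);
  g.c_n = as<double>(pars["c_n"]);
  IntegerVector dims = pars["dims"];
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.N = g.nx * g.ny * g.nz;
  IntegerVector bc = pars["boundary_code"];
  for (int a = 0; a < 3; ++a) g.bc[a] = bc[a];
  if (6.0 * g.p_hop > 1.0)
    stop("phage hop probability violates stability: 6 * D_P * dt / l^2 > 1");
  if (g.c_n > 1.0 / 6.0)
    stop("nutrient diffusion violates stability: D_n * dt / l^2 > 1/6");
  return g;
}

// rpois / rbinom with normal fallbacks outside the ranges the R samplers
// support (counts in whole-volume boxes can exceed .Machine$integer.max).
inline double safe_rpois(double mu) {
  if (mu <= 0.0) return 0.0;
  if (mu < 1e9) return R::rpois(mu);
  double x = R::rnorm(mu, std::sqrt(mu));
  return std::max(0.0, std::floor(x + 0.5));
}

inline double safe_rbinom(double size, double prob) {
  if (size <= 0.0 || prob <= 0.0) return 0.0;
  if (prob >= 1.0) return size;
  if (size < 2e9) return R::rbinom(size, prob);
  double mu = size * prob;
  double x = R::rnorm(mu, std::sqrt(mu * (1.0 - prob)));
  return std::min(size, std::max(0.0, std::floor(x + 0.5)));
}

// Exact inversion samplers for the small-mean draws that dominate sparse
// lattices: one uniform decides the (usually zero) event count. Falls back to
// the standard samplers once the mean is large enough that inversion would
// iterate.
inline double rpois_fast(double mu) {
  if (mu <= 0.0) return 0.0;
  if (mu > 10.0) return safe_rpois(mu);
  double u = unif_rand();
  double p = std::exp(-mu), cdf = p;
  double k = 0.0;
  while (u > cdf && k < 200.0) {
    k += 1.0;
    p *= mu / k;
    cdf += p;
  }
  return k;
}

inline double rbinom_fast(double n, double q) {
  if (n <= 0.0 || q <= 0.0) return 0.0;
  if (q >= 1.0) return n;
  if (n * q > 10.0 || n > 2e9) return safe_rbinom(n, q);
  double u = unif_rand();
  double odds = q / (1.0 - q);
  double p = std::exp(n * std::log1p(-q)), cdf = p;
  double k = 0.0;
  while (u > cdf && k < n) {
    p *= ((n - k) / (k + 1.0)) * odds;
    cdf += p;
    k += 1.0;
  }
  return k;
}

// Index of the neighbour of box (x,y,z) one step along `axis` in direction
// `dir`. Reflective walls and single-box axes map the mover back to its
// source box (zero net flux).
inline int neighbour(int x, int y, int z, int axis, int dir, const EngPars& g) {
  int c[3] = {x, y, z};
  int size[3] = {g.nx, g.ny, g.nz};
  int v = c[axis] + dir;
  if (v < 0 || v >= size[axis]) {
    if (g.bc[axis] == 1) return x + g.nx * (y + g.ny * z);  // bounce back
    v = (v + size[axis]) % size[axis];                      // periodic wrap
  }
  c[axis] = v;
  return c[0] + g.nx * (c[1] + g.ny * c[2]);
}

struct Fields {
  std::vector<double> B, P, n, nc, IT;  // IT = per-box total infected
  std::vector<double> I;                // N x n_stages, stage-major
  double produced, t;
  int N, n_stages;
};

Fields fields_from_state(const List& state, const EngPars& g) {
  Fields f;
  NumericVector B = state["B"], P = state["P"], n = state["n"],
                nc = state["n_c"];
  NumericVector I = state["I"];
  f.N = g.N; f.n_stages = g.n_stages;
  if (B.size() != g.N || I.size() != (R_xlen_t)g.N * g.n_stages)
    stop("state arrays do not match the lattice shape");
  f.B.assign(B.begin(), B.end());
  f.P.assign(P.begin(), P.end());
  f.n.assign(n.begin(), n.end());
  f.nc.assign(nc.begin(), nc.end());
  f.I.assign(I.begin(), I.end());
  f.IT.assign(g.N, 0.0);
  for (int j = 0; j < g.n_stages; ++j)
    for (int i = 0; i < g.N; ++i) f.IT[i] += f.I[i + (size_t)j * g.N];
  f.produced = as<double>(state["produced_cells"]);
  f.t = as<double>(state["t"]);
  return f;
}

List fields_to_state(const Fields& f, const List& state, const EngPars& g) {
  List out = clone(state);
  NumericVector B(f.B.begin(), f.B.end());
  NumericVector P(f.P.begin(), f.P.end());
  NumericVector n(f.n.begin(), f.n.end());
  NumericVector I(f.I.begin(), f.I.end());
  B.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  P.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  n.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  I.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, g.n_stages);
  out["B"] = B; out["P"] = P; out["n"] = n; out["I"] = I;
  out["produced_cells"] = f.produced;
  out["t"] = f.t;
  return out;
}

// One reaction sweep over all boxes (no diffusion). Returns number of lysis
// events; updates `alive` (total B + I) in place.
double react_sweep(Fields& f, const EngPars& g, double& alive) {
  const int N = g.N;
  double lysed_total = 0.0;
  for (int i = 0; i < N; ++i) {
    double b = f.B[i], p = f.P[i], itot = f.IT[i];
    if (b == 0.0 && p == 0.0 && itot == 0.0) continue;
    double nn = f.n[i];
    double m = spatphage::monod(nn, g.K_box);

    // (1) growth, consuming one nutrient unit per division
    if (b > 0.0 && m > 0.0) {
      double G = rpois_fast(g.lambda * b * m * g.dt);
      G = std::min(G, std::floor(nn));
      if (G > 0.0) {
        f.B[i] = b = b + G;
        f.n[i] = nn = nn - G;
        f.produced += G;
        alive += G;
        m = spatphage::monod(nn, g.K_box);
      }
    }

    // (2) free-phage adsorption and infection
    if (p > 0.0) {
      if (g.level <= 3) {
        double A_B = 0.0, A_I = 0.0;
        if (b > 0.0)
          A_B = std::min(rpois_fast(g.eta_box * b * p * g.dt), p);
        if (itot > 0.0)  // superinfection: phage sink only
          A_I = std::min(rpois_fast(g.eta_box * itot * p * g.dt), p - A_B);
        p -= A_B + A_I;
        f.P[i] = p;
        if (g.level == 1) {
          // no latency: adsorption lyses the host instantly
          double inf = std::min(A_B, b);
          f.B[i] = b = b - inf;
          alive -= inf;
          p += g.beta * inf;
          f.P[i] = p;
          lysed_total += inf;
        } else {
          double inf = std::min(A_B, b);
          if (inf > 0.0) {
            f.B[i] = b = b - inf;
            f.I[i] += inf;  // stage 1
            f.IT[i] = itot = itot + inf;
          }
        }
      } else {  // level 4: colony kinetics
        double nce = g.singleton ? (b + itot) : f.nc[i];
        double rate = spatphage::colony_adsorption_rate(b, itot, nce, p,
                                                        g.eta_box);
        if (rate > 0.0) {
          double A = std::min(rpois_fast(rate * g.dt), p);
          p -= A;
          f.P[i] = p;
          double S = spatphage::shielding(b, itot, nce, g.zeta);
          double inf = std::min(rbinom_fast(A, S), b);
          if (inf > 0.0) {
            f.B[i] = b = b - inf;
            f.I[i] += inf;
            f.IT[i] = itot = itot + inf;
          }
        }
      }
    }

    // (3) stage advances, top stage first so a cohort moves at most one
    // stage per step; (4) lysis of the stage-10 out-flux
    if (g.level >= 2 && itot > 0.0 && m > 0.0) {
      double L = 0.0;
      for (int j = g.n_stages - 1; j >= 0; --j) {
        double Ij = f.I[i + (size_t)j * N];
        if (Ij <= 0.0) continue;
        double M = std::min(rpois_fast(g.r * m * Ij * g.dt), Ij);
        if (M <= 0.0) continue;
        f.I[i + (size_t)j * N] = Ij - M;
        if (j + 1 < g.n_stages) f.I[i + (size_t)(j + 1) * N] += M;
        else L = M;
      }
      if (L > 0.0) {
        f.IT[i] = itot = itot - L;
        alive -= L;
        lysed_total += L;
        double progeny = g.beta * L;
        if (g.level <= 3) {
          p += progeny;
          f.P[i] = p;
        } else {
          double escaped = rbinom_fast(progeny, 1.0 - g.alpha);
          double readsorbed = progeny - escaped;
          if (readsorbed > 0.0 && b > 0.0) {
            double nce = g.singleton ? (b + itot) : f.nc[i];
            double S = spatphage::shielding(b, itot, nce, g.zeta);
            double reinf = std::min(rbinom_fast(readsorbed, S), b);
            if (reinf > 0.0) {
              f.B[i] = b = b - reinf;
              f.I[i] += reinf;
              f.IT[i] = itot = itot + reinf;
            }
          }
          p += escaped;
          f.P[i] = p;
        }
      }
    }

    // (5) phage decay
    if (p > 0.0 && g.delta > 0.0) {
      double D = std::min(rpois_fast(g.delta * p * g.dt), p);
      f.P[i] = p - D;
    }

    if (f.B[i] < 0.0 || f.P[i] < 0.0 || f.IT[i] < 0.0 || f.n[i] < 0.0)
      stop("internal error: negative population after reaction sweep");
  }
  return lysed_total;
}

// Multinomial phage random walk: per box, movers ~ Binom(P, 6 p_hop) split
// uniformly over the 6 lattice directions; reflective walls bounce movers
// back to the source box. Exactly conserves the phage total.
void phage_hop(Fields& f, const EngPars& g, std::vector<double>& buf) {
  if (g.p_hop <= 0.0) return;
  const int N = g.N;
  buf.assign(f.P.begin(), f.P.end());
  double q = 6.0 * g.p_hop;
  for (int z = 0, i = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x, ++i) {
        double p = f.P[i];
        if (p <= 0.0) continue;
        double movers = rbinom_fast(p, q);
        if (movers <= 0.0) continue;
        buf[i] -= movers;
        double rem = movers;
        int d = 0;
        for (int axis = 0; axis < 3 && rem > 0.0; ++axis)
          for (int dir = -1; dir <= 1 && rem > 0.0; dir += 2, ++d) {
            double k = (d == 5) ? rem : rbinom_fast(rem, 1.0 / (6 - d));
            if (k > 0.0) {
              buf[neighbour(x, y, z, axis, dir, g)] += k;
              rem -= k;
            }
          }
      }
  f.P.swap(buf);
}

// FTCS nutrient diffusion with zero-flux reflective walls; conservative.
void nutrient_ftcs(Fields& f, const EngPars& g, std::vector<double>& buf) {
  if (g.c_n <= 0.0) return;
  const int N = g.N;
  buf.resize(N);
  for (int z = 0, i = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x, ++i) {
        double lap = 0.0, ni = f.n[i];
        for (int axis = 0; axis < 3; ++axis)
          for (int dir = -1; dir <= 1; dir += 2)
            lap += f.n[neighbour(x, y, z, axis, dir, g)] - ni;
        buf[i] = ni + g.c_n * lap;
      }
  f.n.swap(buf);
}

}  // namespace

// [[Rcpp::export]]
List cpp_react_step(List state, List pars) {
  EngPars g = parse_pars(pars);
  Fields f = fields_from_state(state, g);
  double alive = 0.0;
  for (int i = 0; i < g.N; ++i) alive += f.B[i] + f.IT[i];
  double lysed = react_sweep(f, g, alive);
  f.t += g.dt;
  List out = fields_to_state(f, state, g);
  out.attr("lysed") = lysed;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_diffuse_phages(NumericVector P, List pars) {
  EngPars g = parse_pars(pars);
  Fields f;
  f.P.assign(P.begin(), P.end());
  if ((int)f.P.size() != g.N) stop("phage field does not match lattice shape");
  std::vector<double> buf;
  phage_hop(f, g, buf);
  NumericVector out(f.P.begin(), f.P.end());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_diffuse_nutrient(NumericVector n, List pars) {
  EngPars g = parse_pars(pars);
  Fields f;
  f.n.assign(n.begin(), n.end());
  if ((int)f.n.size() != g.N) stop("nutrient field does not match lattice shape");
  std::vector<double> buf;
  nutrient_ftcs(f, g, buf);
  NumericVector out(f.n.begin(), f.n.end());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return out;
}

// Advance `n_steps` steps, sampling lattice totals every `sample_every`
// steps. Early-exit options: stop_on_extinction freezes the run once
// B + I reaches 0 (absorbing); stop_when_produced stops once the cumulative
// number of bacterial divisions exceeds the threshold (produced_cells is
// non-decreasing, so later values are determined for visibility calls).
// [[Rcpp::export]]
List cpp_run(List state, List pars, int n_steps, int sample_every,
             bool stop_on_extinction, double stop_when_produced) {
  EngPars g = parse_pars(pars);
  Fields f = fields_from_state(state, g);
  std::vector<double> buf;
  double alive = 0.0;
  for (int i = 0; i < g.N; ++i) alive += f.B[i] + f.IT[i];

  int n_samples = n_steps / sample_every;
  NumericMatrix samples(n_samples, 7);
  colnames(samples) = CharacterVector::create(
      "step", "B", "I_total", "P", "n", "produced_cells", "lysed");
  int row = 0, status = 0, stop_step = n_steps;
  double lysed_acc = 0.0;
  bool moving = g.N > 1;

  for (int s = 1; s <= n_steps; ++s) {
    lysed_acc += react_sweep(f, g, alive);
    if (moving) {
      phage_hop(f, g, buf);
      nutrient_ftcs(f, g, buf);
    }
    f.t += g.dt;
    if (s % sample_every == 0) {
      double Bt = 0.0, It = 0.0, Pt = 0.0, nt = 0.0;
      for (int i = 0; i < g.N; ++i) {
        Bt += f.B[i]; It += f.IT[i]; Pt += f.P[i]; nt += f.n[i];
      }
      samples(row, 0) = s; samples(row, 1) = Bt; samples(row, 2) = It;
      samples(row, 3) = Pt; samples(row, 4) = nt;
      samples(row, 5) = f.produced; samples(row, 6) = lysed_acc;
      lysed_acc = 0.0;
      ++row;
    }
    if (stop_on_extinction && alive <= 0.0) { status = 1; stop_step = s; break; }
    if (f.produced > stop_when_produced) { status = 2; stop_step = s; break; }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List final_state = fields_to_state(f, state, g);
  return List::create(
      _["samples"] = samples, _["n_sampled"] = row, _["status"] = status,
      _["stop_step"] = stop_step, _["state"] = final_state);
}
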