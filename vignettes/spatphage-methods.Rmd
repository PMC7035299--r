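---
title: "Models and methods in spatphage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spatphage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatphage)
```

spatphage simulates the transient dynamics of a virulent phage attacking a
susceptible bacterial population in an environment with finite nutrient, at
four nested levels of detail. The question the models address is why phage
epidemics, which in mass-action theory should drive susceptible bacteria to
extinction, routinely leave survivors: time-delayed lysis, spatial separation
of founder cells, and the self-protection of bacteria growing as
microcolonies each moderate the virulence of the phage.

## The four model levels

**Level 1 — well-mixed Lotka-Volterra with nutrient depletion.** Densities
per mL of nutrient $n$ (measured in bacteria-equivalents, i.e. yield 1),
uninfected bacteria $B$ and free phages $P$ evolve as

$$\dot n = -\lambda B\,m,\qquad
  \dot B = \lambda B\,m - \eta B P,\qquad
  \dot P = (\beta - 1)\eta B P - \delta P,$$

with the Monod factor $m = n/(n+K)$. Lysis is instantaneous: each adsorption
consumes one phage and releases $\beta$ new ones.

**Level 2 — Erlang-distributed latency.** Ten sequential infected stages
$I_1,\dots,I_{10}$ separate infection from lysis. Each stage advances at rate
$(10/\tau)\,m$, so the latency is gamma distributed with mean $\tau$ and
coefficient of variation $1/\sqrt{10}\approx 30\%$ when nutrient is
saturating. Scaling the advance rate by the same Monod factor as growth makes
the latency stretch as the culture approaches stationary phase: phages cannot
propagate on starved hosts. Free phages additionally adsorb to
already-infected cells (superinfection, the $-\eta(B+I)P$ sink) without
producing anything.

**Level 3 — space.** The same kinetics run per box of a 3-D lattice, coupled
by diffusion of nutrient ($D_n$) and phages ($D_P$). At the 200 µm box
resolution bacteria are effectively immotile and never hop ($D_B = 0$);
only nutrients and phages move.

**Level 4 — colony-level protection.** Immobilised bacteria grow as
microcolonies: the founder-cell field $n_c$ is frozen at the initial
placement, so each box carries $n_c$ identical colonies of size $(B+I)/n_c$.
Three effects follow:

* *Smoluchowski adsorption.* A diffusion-limited target captures phages in
  proportion to its radius, so the per-box adsorption rate is
  $\eta\,((B+I)/n_c)^{1/3}\, n_c P$ rather than $\eta (B+I) P$.
* *Shielding.* Infected cells accumulate on the colony surface. A phage that
  adsorbs reaches an uninfected cell only with probability
  $S = \min\!\big(B/(B+I),\ \tilde S\big)$, where
  $\tilde S = \exp\!\big(-\tfrac1\zeta\big[((B+I)/n_c)^{1/3} -
  (B/n_c)^{1/3}\big]\big)$ is an absorbing-barrier attenuation through the
  infected layer (thickness measured in bacterial radii) and $\zeta$ is the
  typical penetration depth of a phage in the same units. The
  $B/(B+I)$ cap recovers the unstructured mixture for small or barely
  infected colonies.
* *Readsorption.* Of the $\beta$ progeny from each lysis (the burst size is
  deterministic; no burst-size distribution is modelled), a fraction
  $\alpha$ immediately attacks the parent colony — succeeding with the same
  shielding probability $S$ and otherwise wasted — while $1-\alpha$ escape as
  free phages.

With $n_c = B+I$ (every cell its own colony), $S = B/(B+I)$ and $\alpha = 0$,
level 4 reduces exactly to level 3; the package exposes a
`singleton_colonies` switch so this limit can be exercised even though the
lattice freezes $n_c$ at $t=0$.

## Default parameters

| symbol | meaning | default | plate (P1) set |
|---|---|---|---|
| $\lambda$ | max growth rate | 2 /h | 60/31 /h |
| $\eta$ | adsorption constant | $10^{-8}$ mL/h $= 10^4\ \mu m^3$/h | $1.32\cdot10^4\ \mu m^3$/h |
| $\beta$ | burst size | 100 | 400 |
| $\delta$ | phage decay | 0.1 /h | 0.003 /h |
| $\tau$ | mean latency | 0.5 h | 1 h |
| $n_0$ | initial nutrient | $10^9$/mL | $10^9$/mL (not pinned by the scenario; overridable) |
| $K$ | Monod constant | $n_0/5$ | $n_0/5$ |
| $D_n, D_P$ | diffusion | $10^6$, $10^4\ \mu m^2$/h | $10^6$, $3000\ \mu m^2$/h |
| $\alpha$ | readsorbed fraction | 0.5 | 0.5 |
| $\zeta$ | penetration depth | 1 | scanned over 2.5 / 5 / 10 |
| $\ell$ | box side | 200 µm | 200 µm |
| lattice | shape | $50^3$ (1 cm³) | $50\times50\times2$ (a 400 µm agar layer) |
| $\Delta T$ | time step | $2\cdot10^{-3}$ h | same |

The internal unit system is µm / hours / absolute counts per box; bulk
densities convert through the box volume $\ell^3$ (1 mL $= 10^{12}$ µm³, so
$10^{-8}$ mL/h is exactly $10^4$ µm³/h). `K` is stored as an absolute density
so it can be overridden independently of `n0`.

## The stochastic lattice scheme

The engine is a fixed-step tau-leap. Per box and step, event counts are drawn
from Poisson distributions at start-of-phase rates and clamped to the
available reactants, in the fixed order

1. growth: $G \sim \mathrm{Pois}(\lambda B m\,\Delta T)$, capped by the
   nutrient in the box (one nutrient unit per division);
2. adsorption: total adsorptions from the level's rate law, capped at $P$;
   all adsorbed phages are removed, and a binomial thinning with the level's
   success probability ($B/(B+I)$, or the shielding $S$) converts adsorptions
   into new stage-1 infections, capped at $B$;
3. stage advances $M_i \sim \mathrm{Pois}((10/\tau)m I_i \Delta T)$, applied
   from stage 10 downward so a cohort moves at most one stage per step
   (preserving the Erlang shape at finite $\Delta T$);
4. lysis of the stage-10 out-flux: $\beta$ progeny per event; at level 4 the
   burst is split binomially into escapers and readsorbers;
5. decay $D \sim \mathrm{Pois}(\delta P\,\Delta T)$, capped at $P$.

Phages then perform a multinomial random walk (hop probability
$D_P\Delta T/\ell^2$ per neighbour, six neighbours) and the nutrient field
takes one forward-time central-space (FTCS) step. Both conserve their totals
— exactly for the integer phage field, to floating rounding for the nutrient
— and reflective walls return movers to their source box (zero net flux).
The FTCS scheme is stable when $D\,\Delta T/\ell^2 \le 1/6$; the default
$\Delta T = 2\cdot10^{-3}$ h gives margin $0.05$ for the fastest species
(nutrient), and `check_stability()` exposes the margin. Everything consumes
one seeded RNG stream in a fixed lattice-scan order, so a seed makes a run
bit-reproducible.

Design choices worth stating, since the scheme itself does not force them:

* *Event ordering.* Poisson draws per term are prescribed by the model; the
  order within a step is not. The fixed order above keeps runs deterministic
  given a seed. At the default step all per-event probabilities are $\ll 1$,
  so ordering bias is far below the stochastic scatter (halving $\Delta T$
  moves ensemble means by well under a percent).
* *Capping.* Sampled counts are clamped to the reactants present, with
  adsorption drawn before the infection conversion so phage removal and
  infection stay consistent. This prevents the classic tau-leap pathology of
  negative populations; an internal guard asserts non-negativity after every
  sweep.
* *Superinfection at levels 2–3* is a separate phage sink with rate
  $\eta_{box} I P$, matching the continuum $-\eta(B+I)P$ term by term;
  infected cells are unaffected by being superinfected.
* *Frozen $n_c$.* The founder field stays at its $t=0$ value even if a box's
  bacteria die out; all colony rates vanish anyway when $B+I=0$.
* *Integer draws.* Whether the original scheme drew escape/readsorption
  splits and hop counts binomially or moved deterministic fractions is
  ambiguous; binomial/multinomial draws keep all populations integral, which
  is what makes extinction well defined.
* *$S$ at $B+I=0$* is defined as 1: the value is never consumed (no
  adsorption without cells) and the convention avoids 0/0.
* *Burst size* is exactly $\beta$ per lysis; only the escape/readsorb split
  and the infection conversions are stochastic.

A first-order discretization effect is worth knowing about: with per-step
stage-advance probability $p = (10/\tau) m \Delta T$, the per-stage waiting
time is geometric with mean $\Delta T/p$ (so the mean latency is unbiased at
any step size) but variance $(1-p)\,(\tau/10)^2/m^2$ — a relative deficit of
$p/2$ in the CV. At the production step this is a $\approx 2\%$ effect, so
the latency-statistics checks in the test suite run at $\Delta T = 2\cdot
10^{-4}$ h, where the deficit ($0.2\%$) is below the Monte-Carlo scatter.
This is a numerical-convergence choice, not a model parameter.

## Deterministic companions

Levels 1 and 2 (and a zero-dimensional variant of the colony model,
`rhs_colony_0d()`) are also provided as ODE systems integrated with deSolve's
lsoda at relative tolerance $10^{-8}$, sampled values below $10^{-30}$ of the
state scale clipped to zero. They serve two purposes: they are the batch
-culture models in their own right (the published trajectory figures), and
they are large-population oracles for the stochastic engine — a single-box
run at $B = 10^6$, $P = 10^6$ in 1 mL tracks the staged ODE within 2%
(sup-norm over 5 h, relative to each trajectory's maximum; the normalisation
matters because the epidemic drives $B$ through many orders of magnitude and
pointwise relative error is ill-posed at the collapse).

Whether the published batch trajectories were produced by the ODEs or by a
single-box stochastic run is not stated; both paths are provided and agree at
these population sizes.

## Experiment harnesses and the study conditions

**Trajectories.** `simulate_phage()` at $B_0 = 10^4$/mL, $P_0 = 10^5$/mL:
levels 1–2 collapse (level 2 overshoots to a higher peak first), level 4
survives to a nutrient-limited plateau.

**Survival phase diagrams.** `phase_scan()` runs one seeded simulation per
initial-density cell and reports mean bacterial density, mean nutrient and
the extinction flag at 5, 10 and 15 h, plus the locus where mean nutrient
equals $K$ (`nutrient_contour()`). All levels run stochastically — discrete
populations are what make extinction well defined, and at densities of a few
particles per volume the discreteness is the phenomenon (a "1 PFU/mL" finite
-size effect lets bacteria win the nutrient race).

Note the direction of the penetration-depth effect: a *small* $\zeta$ makes
the infected surface layer opaque, so attacking phages are wasted on
superinfection and the colony is protected; survival curves order
$\zeta = 2.5 \ge 5 \ge 10 \ge$ control.

**Plate replication.** `plate_experiment()` mimics spraying phages on soft
agar: one founder cell per replicate in a $10^4\times10^4\times400$ µm slab
(reflective Z boundaries), phage-free growth to the spray time, $6\cdot10^5$
phages distributed over the top layer, and a visibility call 16 h later —
visible means more than $5\cdot10^5$ *produced* cells, measured as consumed
nutrient because lysed cells still contribute to the visible colony. The
protection-off control runs the level-3 kinetics in the same geometry. The
initial nutrient density for the plate is not pinned by the scenario; the
package keeps the batch default $10^9$/mL (overridable). Spray times are
configurable; the exact grid behind the published survival curves is not
tabulated.

### Desk-scale study sizes

The published maps use a $50^3$ lattice (1 cm³) and thousands of grid cells;
those are cluster-scale. The package's test suite and acceptance script use
sizes chosen so the full suite runs on one CPU in minutes while keeping every
qualitative contrast intact, all at the production densities:

* trajectories on a $16^3$ lattice (0.033 mL) with volume-scaled counts;
* a $4\times4$ (B₀, P₀) grid with $B_0 \in \{10^2,10^4,10^6,10^8\}$ and
  $P_0 \in \{10^3,10^5,10^7,10^9\}$/mL — the decades across which the
  survival boundaries of the three stochastic levels are expected to fall
  (roughly $10^3$–$10^4$ for the well-mixed model, two decades higher with
  space, up to $10^8$ with colonies), two seeds per cell;
* plate scans at 20 replicates per condition (75 for the no-spray control,
  matching the published replication) over spray times {3, 6} h and
  $\zeta \in \{2.5, 5, 10\}$ plus the control (unimpeded growth crosses the
  visibility threshold at about 6.8 h, so later sprays are trivially
  visible).

**What the generator does and does not emulate.** Initial bacteria and
phages are placed uniformly at random; nutrient starts uniform. Real
inocula are often more clumped, which the original authors note would favour
bacteria further. The model excludes cell shoving, resistant mutants,
temperate phages, nutrient release on lysis, and chemotaxis, and treats
$\zeta$ as an input rather than deriving it from single-cell colony
geometry. Passing tests therefore validate the implementation of *this*
model, not the microscopic realism of any particular plate.

## Degenerate inputs, ties, tolerances

* Empty boxes are exact fixed points of the reaction sweep; $D=0$ diffusion
  is the identity; axes of size 1 are self-neighbours (no flux).
* Growth is capped by the nutrient present in the box, so produced cells
  equal consumed nutrient exactly (the accounting identity
  $n_{tot}(0)-n_{tot}(t) = \mathrm{produced}$ holds to floating rounding once
  diffusion is involved).
* Early-exit options: a run can stop when $B+I$ hits zero (extinction is
  absorbing; remaining samples are frozen, phage totals are reported as `NA`
  because the field is no longer advanced) or when `produced_cells` crosses a
  threshold (it is non-decreasing, so visibility calls are already decided).
  Both are conveniences for scans, off by default.
* Counts are stored as integer-valued doubles: whole-volume boxes can exceed
  the 32-bit range, and samplers switch to normal approximations only beyond
  $10^9$ expected events, far above any per-box count the study conditions
  produce.

## Known limitations

* Bacteria never hop ($D_B = 0$); standing-liquid scenarios with slow
  bacterial diffusion are outside the lattice engine (the level-3 PDE's
  $D_B$ terms are intentionally not realised).
* One bacterial strain, one phage; no resistance, no lysogeny.
* The shielding function is the exponential barrier form with the
  small-colony cap; alternative forms are out of scope and $\zeta$ is an
  input parameter.
* Snapshots are JSON containers: human-readable and lossless for the integer
  fields, but not a high-performance array format; at the lattice sizes this
  package targets the files stay small.
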