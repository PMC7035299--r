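#' Monod growth factor
#'
#' The nutrient saturation factor \eqn{n/(n+K)} that multiplies both the
#' bacterial growth rate and the infection stage-advance rate, so that phage
#' development stalls together with host growth as nutrient runs out.
#'
#' @param n Nutrient level (bacteria-equivalents), any non-negative scale.
#' @param K Monod half-saturation constant on the same scale, positive.
#' @return Values in \[0, 1\]; vectorised over `n` and `K`.
#' @export
monod <- function(n, K) {
  stopifnot(all(n >= 0), all(K > 0))
  cpp_monod(as.numeric(n), as.numeric(K))
}

#' Colony shielding functions
#'
#' When a microcolony of `B + I` cells grown from `n_c` founders is partially
#' infected, the infected cells accumulate on its surface and shield the
#' uninfected interior. `shielding_raw()` is the absorbing-barrier form
#' \deqn{\tilde S = \exp\!\left(-\frac{1}{\zeta}\left[\left(\frac{B+I}{n_c}\right)^{1/3}
#'   - \left(\frac{B}{n_c}\right)^{1/3}\right]\right),}
#' the exponent being the infected-layer thickness in bacterial radii and
#' \eqn{\zeta} the typical penetration depth of a phage in the same units.
#' `shielding()` applies the small-colony upper bound
#' \eqn{S = \min(B/(B+I), \tilde S)}, the fraction of uninfected cells that a
#' phage would hit in an unstructured mixture. At `B + I = 0` the value 1 is
#' returned: no adsorption can occur and the convention keeps the function
#' total.
#'
#' @param B Uninfected cells per box (counts or densities).
#' @param I Total infected cells per box.
#' @param n_c Founder (colony) count per box; must be positive whenever
#'   `B + I > 0`.
#' @param zeta Penetration depth in bacterial radii, positive.
#' @return Shielding probabilities; `shielding_raw` in (0, 1\] for `I > 0`,
#'   `shielding` in \[0, 1\]. Vectorised.
#' @export
shielding_raw <- function(B, I, n_c, zeta) {
  stopifnot(all(B >= 0), all(I >= 0), all(zeta > 0))
  cpp_shielding_raw(as.numeric(B), as.numeric(I), as.numeric(n_c),
                    as.numeric(zeta))
}

#' @rdname shielding_raw
#' @export
shielding <- function(B, I, n_c, zeta) {
  stopifnot(all(B >= 0), all(I >= 0), all(zeta > 0))
  cpp_shielding(as.numeric(B), as.numeric(I), as.numeric(n_c),
                as.numeric(zeta))
}

#' Phage adsorption rate to colonies
#'
#' Free phages adsorb to a colony at a rate proportional to its radius
#' (Smoluchowski diffusion-limited capture), i.e. to the colony volume to the
#' power 1/3:
#' \deqn{a = \eta_{box}\,\left(\frac{B+I}{n_c}\right)^{1/3} n_c\, P}
#' events per hour per box. With singleton colonies (`n_c = B + I`) this
#' reduces to the well-mixed total adsorption \eqn{\eta_{box}(B+I)P}.
#'
#' @inheritParams shielding_raw
#' @param P Free phage count per box.
#' @param eta_box Adsorption constant divided by the box volume, 1/h per
#'   phage-cell pair (see [phage_params()]; `eta / box_len^3`).
#' @return Adsorption event rates (per hour per box); 0 whenever `n_c = 0`,
#'   `B + I = 0`, or `P = 0`. Vectorised.
#' @export
colony_adsorption_rate <- function(B, I, n_c, P, eta_box) {
  stopifnot(all(B >= 0), all(I >= 0), all(n_c >= 0), all(P >= 0),
            all(eta_box >= 0))
  cpp_colony_adsorption_rate(as.numeric(B), as.numeric(I), as.numeric(n_c),
                             as.numeric(P), as.numeric(eta_box))
}

#' Partition a burst of progeny phages
#'
#' Each lysis releases exactly `beta` phages. A fraction `alpha` of the
#' progeny readsorbs immediately to the parent colony while the rest escape
#' as free phages; the split is binomial so that
#' `escaped + readsorbed == beta * n_lysed` exactly.
#'
#' @param n_lysed Number of lysis events (non-negative integers, vectorised).
#' @param beta Burst size.
#' @param alpha Readsorption fraction in \[0, 1\].
#' @return A tibble with columns `escaped` and `readsorbed`. Uses the R RNG;
#'   set a seed for reproducibility.
#' @export
partition_burst <- function(n_lysed, beta, alpha) {
  stopifnot(all(n_lysed >= 0), beta >= 0, alpha >= 0, alpha <= 1)
  out <- cpp_partition_burst(as.numeric(n_lysed), beta, alpha)
  tibble(escaped = out$escaped, readsorbed = out$readsorbed)
}
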