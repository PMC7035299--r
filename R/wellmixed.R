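#' Well-mixed state vector
#'
#' Builds the named state vector used by the deterministic models: nutrient
#' `n`, uninfected bacteria `B`, infected stages `I1`...`I10`, and free phages
#' `P`, all densities per mL.
#'
#' @param n,B,P Densities per mL.
#' @param I Vector of infected-stage densities (length `n_stages`), default 0.
#' @param n_stages Number of infected stages.
#' @return A named numeric vector.
#' @export
wm_state <- function(n, B, P, I = rep(0, n_stages), n_stages = 10L) {
  stopifnot(length(I) == n_stages, all(c(n, B, P, I) >= 0))
  setNames(c(n, B, I, P),
           c("n", "B", paste0("I", seq_len(n_stages)), "P"))
}

i_names <- function(state) grep("^I[0-9]+$", names(state), value = TRUE)

#' Right-hand sides of the well-mixed models
#'
#' `rhs_wellmixed()` is the classic Lotka-Volterra batch model with Monod-limited
#' growth and nutrient depletion:
#' \deqn{\dot n = -\lambda B m,\quad \dot B = \lambda B m - \eta B P,\quad
#'   \dot P = (\beta - 1)\eta B P - \delta P,\qquad m = n/(n+K).}
#' `rhs_staged()` adds an Erlang-distributed latent period through 10 sequential
#' infected stages advancing at rate \eqn{(10/\tau)\,m} (latency stretches as
#' nutrient runs out) and a superinfection sink \eqn{-\eta(B+I)P} on the free
#' phages. `rhs_colony_0d()` is the colony-protection model restricted to a
#' single well-mixed compartment: shielded adsorption with the 1/3-exponent
#' colony rate, readsorption of a fraction `alpha` of each burst, and escape
#' fraction `1 - alpha` feeding the free phages.
#'
#' Densities are per mL; the adsorption constant is used in mL/h.
#'
#' @param state Named state vector from [wm_state()] (for `rhs_wellmixed` only
#'   `n`, `B`, `P` are used).
#' @param params A [phage_params()] object.
#' @param n_c Colony density per mL (founder cells), fixed, positive.
#' @return A named numeric vector of time derivatives (per mL per h).
#' @export
rhs_wellmixed <- function(state, params) {
  eta <- params$eta / ML_PER_UM3_INV
  m <- monod(state[["n"]], params$K)
  grow <- params$lambda_max * state[["B"]] * m
  ads <- eta * state[["B"]] * state[["P"]]
  c(n = -grow, B = grow - ads,
    P = (params$beta - 1) * ads - params$delta * state[["P"]])
}

#' @rdname rhs_wellmixed
#' @export
rhs_staged <- function(state, params) {
  eta <- params$eta / ML_PER_UM3_INV
  inm <- i_names(state)
  I <- state[inm]
  Itot <- sum(I)
  m <- monod(state[["n"]], params$K)
  r <- params$n_stages / params$tau
  grow <- params$lambda_max * state[["B"]] * m
  infect <- eta * state[["B"]] * state[["P"]]
  adv <- r * m * I
  dI <- c(infect, adv[-length(adv)]) - adv
  dP <- params$beta * adv[length(adv)] - params$delta * state[["P"]] -
    eta * (state[["B"]] + Itot) * state[["P"]]
  setNames(c(-grow, grow - infect, dI, dP), names(state))
}

#' @rdname rhs_wellmixed
#' @export
rhs_colony_0d <- function(state, n_c, params) {
  stopifnot(n_c > 0)
  eta <- params$eta / ML_PER_UM3_INV
  inm <- i_names(state)
  I <- state[inm]
  Itot <- sum(I)
  B <- state[["B"]]
  m <- monod(state[["n"]], params$K)
  r <- params$n_stages / params$tau
  grow <- params$lambda_max * B * m
  ads <- colony_adsorption_rate(B, Itot, n_c, state[["P"]], eta)
  S <- shielding(B, Itot, n_c, params$zeta)
  lyse <- r * m * I[length(I)]
  infect <- S * (ads + params$alpha * params$beta * lyse)
  adv <- r * m * I
  dI <- c(infect, adv[-length(adv)]) - adv
  dP <- (1 - params$alpha) * params$beta * lyse -
    params$delta * state[["P"]] - ads
  setNames(c(-grow, grow - infect, dI, dP), names(state))
}

#' Integrate a well-mixed model
#'
#' Adaptive-step integration (deSolve's lsoda, relative tolerance 1e-8) of one
#' of the deterministic right-hand sides. Sampled values whose magnitude falls
#' below 1e-30 of the state scale are clipped to zero; the produced-cells
#' accumulator is \eqn{n(0) - n(t)}.
#'
#' @param rhs One of [rhs_wellmixed()], [rhs_staged()], or a function
#'   `function(state, params)` returning derivatives (use a closure to bind
#'   `n_c` for [rhs_colony_0d()]).
#' @param state0 Initial state from [wm_state()].
#' @param t_end End time, h.
#' @param params A [phage_params()] object.
#' @param sample_every Output sampling interval, h.
#' @return A `phage_run` object; its `series` element is a tibble with
#'   columns `time_h`, `n`, `B`, `I_total`, `P`, `produced_cells` (per mL).
#' @export
integrate_wellmixed <- function(rhs, state0, t_end, params,
                                sample_every = 0.1) {
  stopifnot(t_end > 0, sample_every > 0)
  times <- seq(0, t_end, by = sample_every)
  deriv <- function(t, y, parms) list(rhs(y, params))
  scale <- max(abs(state0), params$n0)
  sol <- deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8,
                      atol = 1e-12 * scale)
  if (any(!is.finite(sol)))
    abort("integration failure: non-finite values in the solution")
  sol <- as.data.frame(sol)
  vals <- as.matrix(sol[, -1, drop = FALSE])
  vals[abs(vals) < 1e-30 * scale] <- 0
  vals[vals < 0] <- 0
  inm <- i_names(state0)
  series <- tibble(
    time_h = sol$time,
    n = vals[, "n"],
    B = vals[, "B"],
    I_total = if (length(inm)) rowSums(vals[, inm, drop = FALSE]) else 0,
    P = vals[, "P"],
    produced_cells = state0[["n"]] - vals[, "n"]
  )
  final <- setNames(as.numeric(vals[nrow(vals), ]), colnames(vals))
  new_phage_run(series, state = final, params = params,
                level = NA_integer_, seed = NULL, units = "per_mL",
                volume_ml = NA_real_, engine = "ode")
}

#' Simulate a well-mixed model level
#'
#' Convenience wrapper running level 1 (no latency) or level 2 (10-stage
#' latency) deterministically from initial densities.
#'
#' @param params A [phage_params()] object.
#' @param b0,p0 Initial bacterial and phage densities per mL.
#' @param level 1 or 2.
#' @param t_end End time, h.
#' @param sample_every Output sampling interval, h.
#' @return A `phage_run` object (see [integrate_wellmixed()]).
#' @export
simulate_wellmixed <- function(params, b0, p0, level = 2, t_end = 24,
                               sample_every = 0.1) {
  stopifnot(level %in% 1:2)
  state0 <- wm_state(n = params$n0, B = b0, P = p0,
                     n_stages = params$n_stages)
  rhs <- if (level == 1) rhs_wellmixed else rhs_staged
  if (level == 1) state0 <- state0[c("n", "B", "P")]
  run <- integrate_wellmixed(rhs, state0, t_end, params, sample_every)
  run$level <- as.integer(level)
  run
}
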