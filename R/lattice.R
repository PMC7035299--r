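#' Initialize a lattice state
#'
#' Distributes `B_total` bacteria and `P_total` phages uniformly at random
#' over the lattice boxes (multinomial placement, so totals are conserved
#' exactly), sets a uniform nutrient field of `n0 * box volume`
#' bacteria-equivalents per box, and freezes the founder-colony field
#' `n_c` at the initial bacterial placement.
#'
#' @param params A [phage_params()] object (geometry, `n0`, `dt`, ...).
#' @param B_total,P_total Total initial bacteria and phages (non-negative
#'   integers).
#' @param seed Optional integer seed applied before placement.
#' @return A `lattice_state`: a list with 3-D arrays `B`, `P`, `n`, `n_c`, a
#'   4-D array `I` (last dimension = infected stage), time `t`, the running
#'   `produced_cells` total, `shape`, `box_len`, and the seed used.
#' @export
lattice_init <- function(params, B_total, P_total, seed = params$seed) {
  stopifnot(B_total >= 0, P_total >= 0)
  if (!is.null(seed)) set.seed(seed)
  shape <- params$lattice_shape
  N <- prod(shape)
  B <- array(place_uniform(N, B_total), dim = shape)
  structure(
    list(
      shape = shape,
      box_len = params$box_len,
      t = 0,
      B = B,
      I = array(0, dim = c(shape, params$n_stages)),
      P = array(place_uniform(N, P_total), dim = shape),
      n = array(n0_box(params), dim = shape),
      n_c = B,
      produced_cells = 0,
      seed = seed
    ),
    class = "lattice_state"
  )
}

# Multinomial placement of `total` particles over `n_slots` equiprobable
# slots, batched so draws stay within integer-sized vectors.
place_uniform <- function(n_slots, total) {
  if (n_slots == 1) return(total)
  counts <- numeric(n_slots)
  remaining <- total
  while (remaining > 0) {
    batch <- min(remaining, 1e7)
    idx <- sample.int(n_slots, batch, replace = TRUE)
    counts <- counts + tabulate(idx, nbins = n_slots)
    remaining <- remaining - batch
  }
  counts
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(
    "<lattice_state> %s boxes of %g um, t = %g h\n  B = %g, I = %g, P = %g, n = %g, produced = %g\n",
    paste(x$shape, collapse = " x "), x$box_len, x$t,
    sum(x$B), sum(x$I), sum(x$P), sum(x$n), x$produced_cells))
  invisible(x)
}

#' Advance a lattice state by one time step
#'
#' One tau-leaping step: per box, Poisson-sampled growth, adsorption and
#' infection, infected-stage advances (top stage first), lysis with burst
#' partitioning at level 4, and phage decay, each clamped to the available
#' reactants; then the multinomial phage random walk and FTCS nutrient
#' diffusion. Uses start-of-phase rates, so given a seed the trajectory is
#' bit-reproducible.
#'
#' @param state A `lattice_state`.
#' @param params A [phage_params()] object.
#' @param level Model level: 1 (no latency), 2/3 (free-cell kinetics), 4
#'   (colony protection). Levels 2 and 3 share kinetics; the lattice shape
#'   decides whether a run is well-mixed (single box) or spatial.
#' @param singleton_colonies Level-4 limit check: evaluate colony kinetics
#'   with `n_c` tracking `B + I` (every cell its own colony).
#' @return The updated `lattice_state` at `t + dt`.
#' @export
lattice_step <- function(state, params, level = 4,
                         singleton_colonies = FALSE) {
  pars <- engine_pars(params, level, singleton_colonies)
  st <- cpp_react_step(unclass(state), pars)
  if (prod(state$shape) > 1) {
    st$P <- cpp_diffuse_phages(st$P, pars)
    st$n <- cpp_diffuse_nutrient(st$n, pars)
  }
  class(st) <- "lattice_state"
  st
}

#' Diffusion operators
#'
#' `diffuse_phages()` applies one multinomial random-walk step to the phage
#' field: each phage hops to one of the 6 neighbours with probability
#' \eqn{D_P \Delta T/\ell^2} each; reflective walls bounce movers back. The
#' phage total is conserved exactly. `diffuse_nutrient()` applies one
#' forward-time central-space step to the nutrient field (conservative to
#' floating tolerance).
#'
#' @inheritParams lattice_step
#' @return The updated `lattice_state`.
#' @export
diffuse_phages <- function(state, params) {
  pars <- engine_pars(params, 2)
  if (6 * pars$p_hop > 1)
    abort("hop probability violates 6 * D_P * dt / l^2 <= 1")
  state$P <- cpp_diffuse_phages(state$P, pars)
  state
}

#' @rdname diffuse_phages
#' @export
diffuse_nutrient <- function(state, params) {
  pars <- engine_pars(params, 2)
  state$n <- cpp_diffuse_nutrient(state$n, pars)
  state
}

# Internal constructor for run results shared by the ODE and lattice paths.
new_phage_run <- function(series, state, params, level, seed, units,
                          volume_ml, engine, stopped = "t_end") {
  structure(
    list(series = series, state = state, params = params, level = level,
         seed = seed, units = units, volume_ml = volume_ml, engine = engine,
         stopped = stopped),
    class = "phage_run"
  )
}

#' Run the stochastic lattice engine
#'
#' Advances the state to `t_end`, sampling lattice totals every
#' `sample_every` hours. Identical seed and parameters give bit-identical
#' output.
#'
#' @inheritParams lattice_step
#' @param t_end End time, h (measured from `state$t`).
#' @param sample_every Sampling interval, h; rounded to a whole number of
#'   time steps.
#' @param seed Optional integer seed applied before the run.
#' @param stop_on_extinction Stop early once `B + I` reaches 0 (extinction is
#'   absorbing); remaining sample rows are filled with the frozen bacterial
#'   and nutrient totals and `NA` phages (the phage field is no longer
#'   advanced).
#' @param stop_when_produced Stop early once `produced_cells` exceeds this
#'   threshold (it is non-decreasing); used by the plate harness.
#' @param snapshot_times Times (h) at which to keep full lattice snapshots.
#' @return A `phage_run` with elements `series` (tibble: `time_h`, `n`, `B`,
#'   `I_total`, `P`, `produced_cells`, `lysed` — lattice totals), `state`
#'   (final `lattice_state`), `snapshots`, `params`, `level`, `seed`, and
#'   `stopped` (`"t_end"`, `"extinct"` or `"produced"`).
#' @export
lattice_run <- function(state, params, level = 4, t_end, sample_every = 0.1,
                        seed = NULL, stop_on_extinction = FALSE,
                        stop_when_produced = Inf, snapshot_times = NULL,
                        singleton_colonies = FALSE) {
  stopifnot(t_end > state$t)
  if (!is.null(seed)) set.seed(seed)
  pars <- engine_pars(params, level, singleton_colonies)
  dt <- params$dt
  every <- max(1L, as.integer(round(sample_every / dt)))
  t0 <- state$t

  row0 <- tibble(
    time_h = t0, n = sum(state$n), B = sum(state$B),
    I_total = sum(state$I), P = sum(state$P),
    produced_cells = state$produced_cells, lysed = 0
  )

  snapshots <- list()
  take_snaps <- !is.null(snapshot_times) && length(snapshot_times) > 0

  run_chunk <- function(st, n_steps) {
    cpp_run(unclass(st), pars, n_steps, every,
            stop_on_extinction, stop_when_produced)
  }

  # split the run at snapshot times so full states can be captured
  bounds <- sort(unique(c(
    if (take_snaps) snapshot_times[snapshot_times > t0 & snapshot_times <= t_end],
    t_end)))
  series <- list(row0)
  st <- state
  status <- 0L
  for (b in bounds) {
    n_steps <- as.integer(round((b - st$t) / dt))
    if (n_steps > 0) {
      out <- run_chunk(st, n_steps)
      k <- out$n_sampled
      if (k > 0) {
        sm <- out$samples[seq_len(k), , drop = FALSE]
        series[[length(series) + 1]] <- tibble(
          time_h = st$t + sm[, "step"] * dt,
          n = sm[, "n"], B = sm[, "B"], I_total = sm[, "I_total"],
          P = sm[, "P"], produced_cells = sm[, "produced_cells"],
          lysed = sm[, "lysed"]
        )
      }
      st <- out$state
      class(st) <- "lattice_state"
      status <- out$status
      if (status != 0L) break
    }
    if (take_snaps && b %in% snapshot_times)
      snapshots[[as.character(b)]] <- st
  }

  series <- dplyr::bind_rows(series)
  stopped <- c("t_end", "extinct", "produced")[status + 1L]

  # pad the remaining sample grid after an early stop with the frozen totals
  full_times <- seq(t0, t_end, by = every * dt)
  missing <- full_times[full_times > max(series$time_h) + dt / 2]
  if (length(missing) > 0) {
    series <- dplyr::bind_rows(series, tibble(
      time_h = missing, n = sum(st$n), B = sum(st$B), I_total = sum(st$I),
      P = if (stopped == "extinct") NA_real_ else sum(st$P),
      produced_cells = st$produced_cells, lysed = 0
    ))
  }

  new_phage_run(series, state = st, params = params, level = as.integer(level),
                seed = seed, units = "counts", volume_ml = total_volume_ml(params),
                engine = "stochastic", stopped = stopped) |>
    (\(r) { r$snapshots <- snapshots; r })()
}

#' Simulate a model level from initial densities
#'
#' Top-level entry point matching the four model levels: levels 1-2 run the
#' deterministic well-mixed models by default (set `stochastic = TRUE` for a
#' single-box stochastic run over the same total volume); levels 3-4 run the
#' stochastic lattice engine with initial particles placed uniformly.
#' Densities are per mL and converted to counts through the simulated volume.
#'
#' @param params A [phage_params()] object.
#' @param level Model level 1-4.
#' @param b0,p0 Initial bacterial and phage densities per mL.
#' @param t_end End time, h.
#' @param stochastic For levels 1-2, use the stochastic engine on a single
#'   well-mixed box spanning the whole simulated volume.
#' @param seed Optional integer seed.
#' @param ... Passed on to [lattice_run()].
#' @inheritParams lattice_run
#' @return A `phage_run`.
#' @export
simulate_phage <- function(params, level, b0, p0, t_end = 24,
                           sample_every = 0.1, stochastic = level >= 3,
                           seed = params$seed, ...) {
  stopifnot(level %in% 1:4)
  if (!stochastic) {
    if (level >= 3)
      abort("levels 3-4 are lattice models; no deterministic path is provided")
    return(simulate_wellmixed(params, b0, p0, level, t_end, sample_every))
  }
  p <- params
  if (level <= 2) p <- wellmixed_geometry(params)
  V <- total_volume_ml(p)
  state <- lattice_init(p, round(b0 * V), round(p0 * V), seed = seed)
  lattice_run(state, p, level = level, t_end = t_end,
              sample_every = sample_every, ...)
}

# Single-box geometry spanning the same total volume (well-mixed limit).
wellmixed_geometry <- function(params) {
  side <- params$box_len * prod(params$lattice_shape)^(1 / 3)
  p <- unclass(params)
  p$box_len <- side
  p$lattice_shape <- c(1L, 1L, 1L)
  validate_params(p)
}

#' @export
print.phage_run <- function(x, ...) {
  cat(sprintf("<phage_run> %s engine, level %s, %d samples to t = %g h (%s)\n",
              x$engine, x$level, nrow(x$series), max(x$series$time_h),
              x$stopped))
  print(utils::tail(x$series, 3))
  invisible(x)
}

#' Tidy and summarise simulation runs
#'
#' `tidy()` returns the sampled time series (one row per sample time);
#' `glance()` a one-row summary with final totals/densities, the extinction
#' flag, and the produced-cells accumulator.
#'
#' @param x A `phage_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phage_run
#' @export
tidy.phage_run <- function(x, ...) x$series

#' @rdname tidy.phage_run
#' @method glance phage_run
#' @export
glance.phage_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  tibble(
    engine = x$engine, level = x$level, t_end = last$time_h,
    B_final = last$B, I_final = last$I_total, P_final = last$P,
    n_final = last$n, produced_cells = last$produced_cells,
    extinct = (last$B + last$I_total) < if (x$engine == "ode") 1e-6 else 1,
    stopped = x$stopped
  )
}
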