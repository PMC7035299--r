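#' Semi-stable point of the well-mixed dynamics
#'
#' The density pair at which bacterial division balances adsorption losses
#' (\eqn{\lambda B \approx \eta B P}, so \eqn{P^* = \lambda/\eta}) and phage
#' production balances decay (\eqn{(\beta-1)\eta B P = \delta P}, so
#' \eqn{B^* = \delta/((\beta-1)\eta)}). Around these densities the system
#' changes very slowly, which shapes the survival phase diagram.
#'
#' @param params A [phage_params()] object with `beta > 1`.
#' @return A tibble with columns `P_star` and `B_star`, per mL.
#' @export
semistable_point <- function(params) {
  stopifnot(params$beta > 1)
  eta_ml <- params$eta / ML_PER_UM3_INV
  tibble(
    P_star = params$lambda_max / eta_ml,
    B_star = params$delta / ((params$beta - 1) * eta_ml)
  )
}

#' Survival phase scan over initial densities
#'
#' One seeded run per (`b0`, `p0`, seed) grid cell, recording the mean
#' bacterial density, the mean nutrient density, and the extinction flag
#' (`B + I == 0`, absorbing) at each report time. Initial counts are the
#' densities times the simulated volume, rounded; levels 1-2 run on a single
#' well-mixed box spanning the same volume, levels 3-4 on the lattice, all
#' stochastically (discrete populations give well-defined extinctions).
#'
#' @param params A [phage_params()] object.
#' @param b0_grid,p0_grid Initial densities per mL (use log-spaced grids
#'   within \[1, 1e9\] to reproduce the published maps).
#' @param report_times Report times in h, default `c(5, 10, 15)`.
#' @param level Model level 1-4.
#' @param seeds Integer vector of seeds; one run per seed per cell (the
#'   published maps use a single realization per condition).
#' @param sample_every Sampling interval, h; must divide the report times.
#' @return A `survival_grid` tibble with columns `b0`, `p0`, `seed`, `time_h`,
#'   `mean_B`, `mean_n` (per mL), `extinct`.
#' @seealso [nutrient_contour()] for the mean-nutrient = K locus.
#' @export
phase_scan <- function(params, b0_grid, p0_grid, report_times = c(5, 10, 15),
                       level = 4, seeds = 1L, sample_every = 0.5) {
  stopifnot(all(b0_grid >= 0), all(p0_grid >= 0), all(report_times > 0))
  p <- if (level <= 2) wellmixed_geometry(params) else params
  V <- total_volume_ml(p)
  t_end <- max(report_times)

  cells <- tidyr::expand_grid(b0 = b0_grid, p0 = p0_grid, seed = seeds)
  res <- purrr::pmap(cells, function(b0, p0, seed) {
    state <- lattice_init(p, round(b0 * V), round(p0 * V), seed = seed)
    run <- lattice_run(state, p, level = level, t_end = t_end,
                       sample_every = sample_every,
                       stop_on_extinction = TRUE)
    s <- run$series
    idx <- vapply(report_times, function(tt) which.min(abs(s$time_h - tt)), 1L)
    tibble(
      b0 = b0, p0 = p0, seed = seed, time_h = report_times,
      mean_B = s$B[idx] / V,
      mean_n = s$n[idx] / V,
      extinct = (s$B[idx] + s$I_total[idx]) == 0
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("survival_grid", class(out))
  attr(out, "params") <- params
  attr(out, "level") <- level
  out
}

#' Nutrient contour of a phase scan
#'
#' For each initial bacterial density and report time, interpolates (in log10
#' of the initial phage density) the locus where the system-averaged nutrient
#' equals the Monod constant `K`: above the contour the bulk of the nutrient
#' has been converted to biomass and the system is near steady state.
#'
#' @param grid A `survival_grid` from [phase_scan()].
#' @param K Monod constant per mL; defaults to the scan's parameter value.
#' @return A tibble with columns `time_h`, `b0`, `p0_at_K` (`NA` where the
#'   contour does not cross the scanned range).
#' @export
nutrient_contour <- function(grid, K = attr(grid, "params")$K) {
  grid %>%
    group_by(.data$time_h, .data$b0, .data$p0) %>%
    summarise(mean_n = mean(.data$mean_n), .groups = "drop") %>%
    group_by(.data$time_h, .data$b0) %>%
    arrange(.data$p0, .by_group = TRUE) %>%
    summarise(
      p0_at_K = {
        mn <- .data$mean_n
        lp <- log10(.data$p0)
        if (all(mn > K) || all(mn < K)) NA_real_
        else 10^approx(mn, lp, xout = K, ties = "ordered")$y
      },
      .groups = "drop"
    )
}

#' Soft-agar plate replication
#'
#' Replicates plating experiments in which single bacteria grow to
#' microcolonies in a thin soft-agar layer before phages are sprayed on top.
#' Each replicate starts with one bacterium in the centre box of the bottom
#' layer; the colony grows phage-free until `spray_time`, then `p_spray`
#' phages are distributed uniformly over the top Z-layer, and the run
#' continues for another `t_grow` hours. A replicate is scored visible when
#' the number of produced cells (measured as consumed nutrient, since lysed
#' cells also contribute to colony size) exceeds `visibility_threshold`.
#'
#' @param params Plate parameters, typically [p1_plate_params()].
#' @param spray_times Phage addition times, h (vectorised).
#' @param zeta_values Penetration depths to scan (vectorised). Colony
#'   protection uses level 4; `protection = FALSE` rows (the control) run
#'   level 3 instead.
#' @param replicates Stochastic replicates per condition.
#' @param p_spray Number of phages sprayed, default 6e5.
#' @param visibility_threshold Produced-cells threshold for a visible colony,
#'   default 5e5 (approximately a 50 um colony radius).
#' @param t_grow Incubation time after spraying, h, default 16.
#' @param include_control Add the protection-off (level 3) control rows.
#' @param seed Base seed; replicate r of each condition uses `seed + r`.
#' @return A `plate_result` tibble with columns `spray_time`, `zeta`,
#'   `protection`, `replicates`, `n_visible`, `visible_fraction`,
#'   `standard_error` (binomial, \eqn{\sqrt{f(1-f)/n}}).
#' @export
plate_experiment <- function(params, spray_times, zeta_values = c(2.5, 5, 10),
                             replicates = 75, p_spray = 6e5,
                             visibility_threshold = 5e5, t_grow = 16,
                             include_control = TRUE, seed = 1L) {
  conds <- tidyr::expand_grid(
    spray_time = spray_times,
    tibble(zeta = zeta_values, protection = TRUE)
  )
  if (include_control) {
    conds <- bind_rows(
      conds,
      tibble(spray_time = spray_times, zeta = NA_real_, protection = FALSE))
  }
  res <- purrr::pmap(
    list(conds$spray_time, conds$zeta, conds$protection, seq_len(nrow(conds))),
    function(spray_time, zeta, protection, cond_idx) {
    vis <- vapply(seq_len(replicates), function(r) {
      plate_replicate(params, spray_time, zeta, protection, p_spray,
                      visibility_threshold, t_grow,
                      seed = (seed + 7919L * cond_idx + r) %% .Machine$integer.max)
    }, logical(1))
    f <- mean(vis)
    tibble(
      spray_time = spray_time, zeta = zeta, protection = protection,
      replicates = replicates, n_visible = sum(vis), visible_fraction = f,
      standard_error = sqrt(f * (1 - f) / replicates)
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("plate_result", class(out))
  attr(out, "params") <- params
  out
}

# One plate replicate; returns TRUE when the colony reaches visible size.
plate_replicate <- function(params, spray_time, zeta, protection, p_spray,
                            visibility_threshold, t_grow, seed) {
  p <- unclass(params)
  if (protection && !is.na(zeta)) p$zeta <- zeta
  p <- validate_params(p)
  level <- if (protection) 4 else 3
  state <- make_fixture("single_colony_plate", p, seed = seed)
  if (spray_time > 0) {
    run <- lattice_run(state, p, level = level, t_end = spray_time,
                       sample_every = spray_time,
                       stop_when_produced = visibility_threshold)
    state <- run$state
    if (state$produced_cells > visibility_threshold) return(TRUE)
  }
  state <- spray_phages(state, p_spray)
  run <- lattice_run(state, p, level = level,
                     t_end = spray_time + t_grow, sample_every = t_grow,
                     stop_on_extinction = TRUE,
                     stop_when_produced = visibility_threshold)
  run$state$produced_cells > visibility_threshold
}

#' Spray phages onto the top of the agar layer
#'
#' Distributes `p_total` phages multinomially over the boxes of the top
#' Z-layer (the agar surface), mimicking a uniform spray.
#'
#' @param state A `lattice_state` with plate geometry.
#' @param p_total Number of phages to add.
#' @return The updated `lattice_state`.
#' @export
spray_phages <- function(state, p_total) {
  stopifnot(p_total >= 0)
  nx <- state$shape[1]; ny <- state$shape[2]; nz <- state$shape[3]
  layer <- place_uniform(nx * ny, p_total)
  state$P[, , nz] <- state$P[, , nz] + array(layer, dim = c(nx, ny))
  state
}

#' Vertical phage profile
#'
#' Sums the phage field over X and Y per Z-layer, showing how sprayed phages
#' diffuse down into the agar over time.
#'
#' @param state A `lattice_state`.
#' @return A tibble with columns `z_index`, `z_um` (box centre), `P`.
#' @export
vertical_phage_profile <- function(state) {
  nz <- state$shape[3]
  counts <- vapply(seq_len(nz), function(z) sum(state$P[, , z]), numeric(1))
  tibble(
    z_index = seq_len(nz),
    z_um = (seq_len(nz) - 0.5) * state$box_len,
    P = counts
  )
}
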