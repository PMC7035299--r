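test_that("semi-stable point is the closed-form balance of rates", {
  p <- default_params()
  sp <- semistable_point(p)
  expect_identical(sp$P_star, 2 / 1e-8)          # lambda / eta = 2e8 per mL
  expect_identical(sp$B_star, 0.1 / (99 * 1e-8)) # delta / ((beta-1) eta)
  expect_equal(sp$B_star, 1e5, tolerance = 0.02)
  # burst size to infinity: marginal bacterial density vanishes
  expect_lt(semistable_point(default_params(beta = 1e15))$B_star, 1e-6)
  expect_error(semistable_point(default_params(beta = 1)))
})

test_that("the well-mixed system is semi-stable at (B*, P*)", {
  p <- default_params()
  sp <- semistable_point(p)
  st <- c(n = p$n0, B = sp$B_star, P = sp$P_star)
  d <- rhs_wellmixed(st, p)
  # net rates are small fractions of the one-way fluxes they balance:
  # division vs adsorption for B, burst production vs decay for P
  gross_B <- p$lambda_max * sp$B_star
  gross_P <- p$delta * sp$P_star
  expect_lt(abs(d[["B"]]), 0.2 * gross_B)
  expect_lt(abs(d[["P"]]), 0.05 * gross_P)
  # and both populations drift by far less than their batch-culture swings
  run <- simulate_wellmixed(p, b0 = sp$B_star, p0 = sp$P_star, level = 1,
                            t_end = 3, sample_every = 0.5)
  s <- tidy(run)
  expect_true(all(s$B > 0.3 * sp$B_star & s$B < 3 * sp$B_star))
  expect_true(all(s$P > 0.3 * sp$P_star & s$P < 3 * sp$P_star))
})

test_that("phase scan records nesting dead regions and falling nutrient", {
  p <- tiny_params(shape = c(6L, 6L, 6L))
  g <- phase_scan(p, b0_grid = c(1e4, 1e6), p0_grid = c(1e4, 1e7),
                  report_times = c(1, 2, 4), level = 3, seeds = 1:2)
  expect_s3_class(g, "survival_grid")
  expect_equal(nrow(g), 2 * 2 * 2 * 3)
  by_cell <- split(g, interaction(g$b0, g$p0, g$seed))
  for (cell in by_cell) {
    cell <- cell[order(cell$time_h), ]
    expect_true(all(diff(cell$mean_n) <= 1e-9))    # nutrient non-increasing
    expect_true(all(diff(cell$extinct) >= 0))      # extinction absorbing
  }
})

test_that("very low phage loads let bacteria win the nutrient race", {
  p <- tiny_params(shape = c(6L, 6L, 6L))
  # fewer than one phage in the simulated volume
  g <- phase_scan(p, b0_grid = 1e5, p0_grid = 1, report_times = c(12),
                  level = 3, seeds = 1L)
  expect_false(any(g$extinct))
  expect_lt(g$mean_n[g$time_h == 12], p$K)  # bulk of nutrient consumed
})

test_that("nutrient contour interpolates the mean_n = K locus", {
  g <- tibble::tibble(
    b0 = 1, p0 = rep(10^(0:3), each = 1), time_h = 5, seed = 1,
    mean_B = 0, extinct = FALSE,
    mean_n = c(1e5, 1e6, 1e7, 1e8)
  )
  class(g) <- c("survival_grid", class(g))
  attr(g, "params") <- default_params(K = 1e6)
  ct <- nutrient_contour(g)
  expect_equal(ct$p0_at_K, 10)  # exact grid point
  attr(g, "params") <- default_params(K = 1e12)
  expect_true(is.na(nutrient_contour(g)$p0_at_K))
})

test_that("spatial heterogeneity delays the well-mixed extinction", {
  p <- default_params(lattice_shape = c(12L, 12L, 12L))
  V <- total_volume_ml(p)
  # deterministic well-mixed reference: time at which B falls below 1 cell
  ode <- tidy(simulate_wellmixed(p, 1e4, 1e5, level = 2, t_end = 15,
                                 sample_every = 0.1))
  t_ode <- min(ode$time_h[(ode$B + ode$I_total) * V < 1])
  r3 <- simulate_phage(p, level = 3, b0 = 1e4, p0 = 1e5, t_end = 15,
                       sample_every = 0.25, seed = 19,
                       stop_on_extinction = TRUE)
  s3 <- tidy(r3)
  gone <- s3$time_h[(s3$B + s3$I_total) == 0]
  t_lattice <- if (length(gone)) min(gone) else Inf
  expect_gt(t_lattice, t_ode)
})

test_that("phage spraying loads the top layer only and conserves totals", {
  pp <- p1_plate_params()
  st <- make_fixture("single_colony_plate", pp, seed = 2)
  set.seed(5)
  st2 <- spray_phages(st, 6e5)
  prof <- vertical_phage_profile(st2)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$P, c(0, 6e5))       # all mass at Z = 400 um
  expect_equal(prof$z_um, c(100, 300))  # box centres
  expect_equal(sum(st2$P), 6e5)
})

test_that("two-layer plate relaxes like the reflecting two-state walk", {
  pp <- p1_plate_params(eta = 0, delta = 0, lambda_max = 0)
  st <- make_fixture("single_colony_plate", pp, seed = 3)
  set.seed(8)
  st <- spray_phages(st, 6e5)
  q <- spatphage:::engine_pars(pp, 2)$p_hop  # per-neighbour hop probability
  k <- 200
  run <- lattice_run(st, pp, level = 2, t_end = k * pp$dt,
                     sample_every = k * pp$dt, seed = 9)
  top <- vertical_phage_profile(run$state)$P[2] / 6e5
  # 2x2 Markov chain with switch probability q per step:
  # top occupancy 1/2 + 1/2 (1 - 2q)^k
  expect_equal(top, 0.5 + 0.5 * (1 - 2 * q)^k, tolerance = 0.005)
})

test_that("plate replicates without phages always reach visible size", {
  pp <- p1_plate_params()
  res <- plate_experiment(pp, spray_times = 0, zeta_values = 10,
                          replicates = 2, p_spray = 0,
                          include_control = FALSE, seed = 12)
  expect_equal(res$visible_fraction, 1)
  expect_equal(res$standard_error, 0)
})

test_that("an immediate heavy spray kills the founder cell", {
  pp <- p1_plate_params()
  res <- plate_experiment(pp, spray_times = 0, zeta_values = 1,
                          replicates = 3, p_spray = 5e7,
                          include_control = FALSE, seed = 13)
  expect_equal(res$visible_fraction, 0)
})
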