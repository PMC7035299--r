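test_that("rhs_wellmixed matches direct arithmetic and its conservation structure", {
  p <- default_params()
  st <- c(n = 1e9, B = 1e4, P = 1e5)
  d <- rhs_wellmixed(st, p)
  expect_equal(d[["B"]], 2e4 * (5 / 6) - 1e-8 * 1e4 * 1e5)
  expect_equal(d[["n"]], -2e4 * (5 / 6))
  expect_equal(d[["P"]], 99 * 1e-8 * 1e4 * 1e5 - 0.1 * 1e5)
  # without phages, biomass gain mirrors nutrient loss
  d0 <- rhs_wellmixed(c(n = 5e8, B = 1e6, P = 0), p)
  expect_equal(d0[["B"]], -d0[["n"]])
  # without bacteria, only phage decay remains
  db <- rhs_wellmixed(c(n = 5e8, B = 0, P = 1e4), p)
  expect_equal(unname(db), c(0, 0, -0.1 * 1e4))
})

test_that("rhs_staged freezes infection progress without nutrient", {
  p <- default_params()
  st <- wm_state(n = 0, B = 1e5, P = 1e6, I = rep(1e3, 10))
  d <- rhs_staged(st, p)
  expect_equal(d[["n"]], 0)
  # B only loses to adsorption
  expect_equal(d[["B"]], -1e-8 * 1e5 * 1e6)
  # stages frozen except new infections into I1
  expect_equal(d[["I1"]], 1e-8 * 1e5 * 1e6)
  expect_equal(unname(d[paste0("I", 2:10)]), rep(0, 9))
  # free phages: decay plus the superinfection sink -eta (B+I) P
  expect_equal(d[["P"]], -0.1 * 1e6 - 1e-8 * (1e5 + 1e4) * 1e6)
})

test_that("rhs_staged reduces to pure Monod growth without phages", {
  p <- default_params()
  st <- wm_state(n = 1e9, B = 1e4, P = 0)
  d <- rhs_staged(st, p)
  expect_equal(d[["B"]], p$lambda_max * 1e4 * (5 / 6))
  expect_equal(sum(abs(d[paste0("I", 1:10)])), 0)
})

test_that("rhs_colony_0d equals rhs_staged in the singleton-colony limit", {
  p <- default_params(alpha = 0)
  for (seed in 1:20) {
    st <- random_wm_state(seed)
    nc <- st[["B"]] + sum(st[grep("^I", names(st))])
    expect_equal(rhs_colony_0d(st, n_c = nc, p), rhs_staged(st, p),
                 tolerance = 1e-12)
  }
})

test_that("rhs_colony_0d shares the nutrient/biomass coupling and pure growth", {
  p <- default_params()
  st <- wm_state(n = 1e9, B = 1e4, P = 0)
  d <- rhs_colony_0d(st, n_c = 1e3, p)
  expect_equal(d[["B"]], -d[["n"]])
  st2 <- random_wm_state(3)
  d2 <- rhs_colony_0d(st2, n_c = 100, p)
  expect_equal(d2[["n"]], -p$lambda_max * st2[["B"]] *
                 monod(st2[["n"]], p$K))
})

test_that("integration conserves biomass and keeps states non-negative", {
  p <- default_params()
  run <- simulate_wellmixed(p, b0 = 1e4, p0 = 0, level = 1, t_end = 30)
  s <- tidy(run)
  expect_true(all(s$B >= 0 & s$n >= 0 & s$P >= 0))
  expect_equal(s$B[nrow(s)] + s$n[nrow(s)], 1e9 + 1e4, tolerance = 1e-6)
  expect_equal(s$produced_cells, 1e9 - s$n)
})

test_that("latency makes the collapse later and larger (batch trajectories)", {
  p <- default_params()
  r1 <- simulate_wellmixed(p, 1e4, 1e5, level = 1, t_end = 20)
  r2 <- simulate_wellmixed(p, 1e4, 1e5, level = 2, t_end = 20)
  s1 <- tidy(r1); s2 <- tidy(r2)
  # both well-mixed models end in collapse (well below one cell per mL)
  expect_lt(s1$B[nrow(s1)], 1)
  expect_lt(s2$B[nrow(s2)], 1)
  # the 10-stage latency lets bacteria overshoot to a higher peak
  expect_gt(max(s2$B), max(s1$B))
  # and phages overwhelm the bacteria in both
  expect_gt(max(s1$P), 1e9)
})

test_that("eq2 approaches eq1 as the latency vanishes", {
  p1 <- default_params()
  p2 <- default_params(tau = 1e-3)
  r1 <- tidy(simulate_wellmixed(p1, 1e4, 1e3, level = 1, t_end = 3))
  r2 <- tidy(simulate_wellmixed(p2, 1e4, 1e3, level = 2, t_end = 3))
  expect_equal(r2$B, r1$B, tolerance = 0.03)
  expect_equal(r2$n, r1$n, tolerance = 0.03)
  expect_equal(r2$P, r1$P, tolerance = 0.03)
})

test_that("integration failure is signalled on non-finite dynamics", {
  p <- default_params()
  boom <- function(state, params) setNames(rep(NaN, length(state)),
                                           names(state))
  expect_error(
    suppressWarnings(integrate_wellmixed(boom, wm_state(1e9, 1e4, 0), 1, p)))
})
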