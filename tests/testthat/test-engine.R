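test_that("electrode activation samples the nearest pixel for active electrodes only", {
  sim <- desk_sim()
  black <- matrix(0, 200, 200)
  white <- matrix(1, 200, 200)
  all_e <- seq_len(100)

  expect_true(all(electrode_activation(black, sim$array, all_e, sim$spec) == 0))

  # one 5-group raster group active on a white frame: exactly 20 amplitudes at 1
  sched <- checkerboard_schedule(sim$array, 5)
  act <- electrode_activation(white, sim$array,
                              active_electrodes(sched, sim$array, 0), sim$spec)
  expect_equal(sum(act == 1), 20)
  expect_equal(sum(act == 0), 80)

  # monotonicity probe: brightening the pixel at one electrode's location
  # raises that amplitude only
  fr <- matrix(0.2, 200, 200)
  e <- 34
  cc <- round(sim$array$x_um[e] / 280 / (60 / 200) + 100.5)
  rr <- round(100.5 - sim$array$y_um[e] / 280 / (60 / 200))
  fr2 <- fr; fr2[rr, cc] <- 0.9
  a1 <- electrode_activation(fr, sim$array, all_e, sim$spec)
  a2 <- electrode_activation(fr2, sim$array, all_e, sim$spec)
  expect_gt(a2[e], a1[e])
  expect_equal(a2[-e], a1[-e])
})

test_that("spatial percept reduces to the closed-form radial Gaussian as lambda -> 0", {
  sim <- desk_sim_with_params(rho = 300, lam = 1)
  a <- setNames(numeric(100), sim$array$electrode_id)
  a[45] <- 1
  f <- spatial_percept(a, sim$basis)
  gx <- sim$basis$grid_x_deg * 280
  gy <- sim$basis$grid_y_deg * 280
  d2 <- outer(gy - sim$array$y_um[45], gx - sim$array$x_um[45],
              function(y, x) x^2 + y^2)
  expect_lt(max(abs(f - exp(-d2 / (2 * 300^2)))), 1e-3)
  # single unit-amplitude electrode never exceeds 1
  expect_lte(max(f), 1)
})

test_that("multi-electrode percepts respect the max/sum envelope and monotonicity", {
  sim <- desk_sim()
  ids <- sim$array$electrode_id
  zero <- setNames(numeric(100), ids)
  expect_true(all(spatial_percept(zero, sim$basis) == 0))

  a1 <- zero; a1[45] <- 1
  a2 <- zero; a2[57] <- 0.7
  f1 <- spatial_percept(a1, sim$basis)
  f2 <- spatial_percept(a2, sim$basis)
  f12 <- spatial_percept(a1 + a2, sim$basis)
  # bounded between the pointwise max and the pointwise sum, everywhere
  expect_true(all(f12 >= pmax(f1, f2) - 1e-12))
  expect_true(all(f12 <= f1 + f2 + 1e-12))

  # raising one amplitude never decreases brightness anywhere
  a3 <- a1 + a2; a3[57] <- 0.9
  f3 <- spatial_percept(a3, sim$basis)
  expect_true(all(f3 >= f12 - 1e-12))

  # global bound for amplitudes in [0, 1]
  ones <- setNames(rep(1, 100), ids)
  expect_lte(max(spatial_percept(ones, sim$basis)), 100)
})

test_that("temporal model matches the exact linear solution and converges at first order", {
  p <- temporal_params("5Hz")
  expect_equal(unlist(p), c(tau_n = 0.2, tau_b = 5, alpha = 0.2))
  expect_equal(temporal_params("20Hz")$alpha, 0.25)

  # zero input from zero state stays identically zero
  out0 <- integrate_temporal(matrix(0, 1, 100), p, 1 / 90)
  expect_true(all(out0 == 0))

  # constant input: Euler tracks the closed-form solution; halving the step
  # roughly halves the error (first-order convergence)
  err_at <- function(dt) {
    Tn <- round(5 / dt)
    out <- integrate_temporal(matrix(1, 1, Tn), p, dt)
    ex <- exact_brightness_const((1:Tn) * dt, p)
    max(abs(out[1, ] - ex)) / max(ex)
  }
  e1 <- err_at(1 / 90)
  e2 <- err_at(1 / 180)
  expect_lt(e1, 0.02)
  expect_lt(e2, 0.6 * e1)

  # arbitrary input: Euler vs the matrix-exponential propagator
  set.seed(3)
  u <- runif(450)
  out <- integrate_temporal(matrix(u, 1), p, 1 / 90)
  ex <- exact_brightness_series(u, p, 1 / 90)
  expect_lt(max(abs(out[1, ] - ex)) / max(ex), 0.03)

  expect_error(integrate_temporal(matrix(1, 1, 2), p, dt = 0), "dt")
  expect_error(temporal_step(NULL, 1, p, dt = -1), "dt")
})

test_that("sustained input fades: 5Hz to its zero steady state, 20Hz clamped at zero", {
  p5 <- temporal_params("5Hz")
  # algebraic steady state b* = b_I (1 - alpha/tau_n) / tau_b = 0
  expect_equal(1 * (1 - p5$alpha / p5$tau_n) / p5$tau_b, 0)
  out <- integrate_temporal(matrix(1, 1, 60 * 90), p5, 1 / 90)
  expect_lt(abs(out[1, 60 * 90]), 0.01 * max(out))

  # 20Hz preset: pre-clamp steady state is negative, clamp pins b at 0
  p20 <- temporal_params("20Hz")
  expect_lt(1 * (1 - p20$alpha / p20$tau_n) / p20$tau_b, 0)
  out2 <- integrate_temporal(matrix(1, 1, 80 * 90), p20, 1 / 90)
  expect_equal(out2[1, 80 * 90], 0)
  expect_true(all(out2 >= 0))
})

test_that("temporal response is linear before the clamp binds", {
  p <- temporal_params("5Hz")  # transient stays non-negative: clamp inactive
  u <- matrix(0.3, 1, 200)
  out1 <- integrate_temporal(u, p, 1 / 90)
  out2 <- integrate_temporal(3 * u, p, 1 / 90)
  expect_equal(unclass(out2), 3 * unclass(out1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # superposition against the exact propagator on random inputs
  set.seed(8)
  ua <- runif(100); ub <- runif(100)
  ea <- exact_brightness_series(ua, p, 1 / 90)
  eb <- exact_brightness_series(ub, p, 1 / 90)
  eab <- exact_brightness_series(ua + ub, p, 1 / 90)
  expect_equal(eab, ea + eb, tolerance = 1e-10)
  oab <- integrate_temporal(matrix(ua + ub, 1), p, 1 / 90)
  oa <- integrate_temporal(matrix(ua, 1), p, 1 / 90)
  ob <- integrate_temporal(matrix(ub, 1), p, 1 / 90)
  expect_equal(unclass(oab), unclass(oa) + unclass(ob), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the temporal model smooths raster group transitions", {
  cfg_on <- desk_cfg("main", "horizontal", duration_s = 1)
  cfg_off <- desk_cfg("main", "horizontal", duration_s = 1,
                      temporal = list(on = FALSE))
  sim <- desk_sim()
  stim <- render_optotype("E", duration_s = 1)
  clip_on <- run_simulation(stim, NULL, cfg_on, sim = sim)
  clip_off <- run_simulation(stim, NULL, cfg_off, sim = sim)
  jump <- function(cl) stats::var(diff(apply(cl$frames, 3, sum)))
  expect_lt(jump(clip_on), jump(clip_off))
})
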