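# Shared desk-scale fixtures, built once per test run.
#
# The evaluation scale (0.5 deg percept grid, 300 axon bundles, short clips)
# keeps the suite fast; model structure and defaults are exercised separately.

.fixtures <- new.env(parent = emptyenv())

desk_cfg <- function(condition = "main", pattern = "checkerboard",
                     duration_s = 1, seed = 1, ...) {
  ov <- list(...)
  merge_over <- function(base, extra)
    if (is.null(extra)) base else utils::modifyList(base, extra)
  args <- c(
    list(condition, pattern, seed = seed,
         retina = merge_over(list(step_deg = 0.5), ov$retina),
         axon = merge_over(list(n_axons = 300), ov$axon),
         stimulus = merge_over(list(duration_s = duration_s), ov$stimulus)),
    ov[setdiff(names(ov), c("retina", "axon", "stimulus"))])
  do.call(sim_config, args)
}

# one cached geometry build shared by every test that uses the default
# rho = 300 / lam = 1000 parameters
desk_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- build_sim(desk_cfg())
  .fixtures$sim
}

# same geometry, different axon-map parameters (basis rebuilt, paths reused)
desk_sim_with_params <- function(rho, lam) {
  base <- desk_sim()
  sim <- base
  sim$params <- axon_map_params(rho, lam)
  sim$basis <- phosphene_basis(base$array, base$axons, sim$params)
  sim
}

# closed-form solution of the coupled leaky integrators for constant input
# b_I from the zero state (independent oracle: distinct decay rates, lower
# triangular system; no numerical integration involved)
exact_brightness_const <- function(t, params, b_I = 1) {
  with(params, {
    A <- b_I * (1 - alpha / tau_n) / tau_b
    C1 <- alpha * b_I / tau_n / (tau_b - tau_n)
    A + C1 * exp(-tau_n * t) + (-A - C1) * exp(-tau_b * t)
  })
}

# exact one-step propagator for the same system with piecewise-constant
# input (matrix-exponential of the 2x2 lower-triangular generator, written
# in closed form), for arbitrary input sequences
exact_brightness_series <- function(u, params, dt) {
  l1 <- -params$tau_n; l2 <- -params$tau_b
  e1 <- exp(l1 * dt); e2 <- exp(l2 * dt)
  m21 <- -params$alpha * (e1 - e2) / (l1 - l2)
  A <- matrix(c(l1, -params$alpha, 0, l2), 2, 2)
  Phi <- matrix(c(e1, m21, 0, e2), 2, 2)
  psi <- solve(A, (Phi - diag(2))) %*% c(1, 1)
  x <- c(0, 0)
  out <- numeric(length(u))
  for (i in seq_along(u)) {
    x <- Phi %*% x + psi * u[i]
    out[i] <- x[2]
  }
  out
}
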