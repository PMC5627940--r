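test_that("sigmoid transfer has the right midpoint, limits and monotonicity", {
  p <- mass_params()
  # midpoint: V = Vd gives q/2 analytically for the logistic form
  expect_equal(sigmoid_transfer(7, 7, q = p$q, r = p$r), p$q / 2)
  # saturation
  expect_lt(sigmoid_transfer(-1e3, 7), 1e-10)
  expect_equal(sigmoid_transfer(1e3, 7), mass_params()$q, tolerance = 1e-10)
  # lowering the threshold raises excitability at fixed Vm
  expect_gt(sigmoid_transfer(6, 5), sigmoid_transfer(6, 7))
  # randomized monotonicity in Vm and anti-monotonicity in Vd
  set.seed(11)
  vm <- sort(rnorm(1000, 7, 4))
  vd <- runif(1000, 3, 11)
  s <- sigmoid_transfer(vm, 7)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < mass_params()$q))
  s_lo <- sigmoid_transfer(5, vd - 0.5)
  s_hi <- sigmoid_transfer(5, vd)
  expect_true(all(s_lo > s_hi))
  expect_error(sigmoid_transfer(NaN, 7), "finite")
})

test_that("synaptic filters converge to their DC gain and peak at 1/a", {
  p <- mass_params(P_sd = 0)
  st <- mass_state(params = p)
  dt <- 5e-4
  # constant unit drive: steady state is the kernel integral A/a (resp. B/b)
  for (i in seq_len(round(0.5 / dt))) {
    st <- impulse_response_step(st, drive_e = 1, drive_i = 1, p, dt)
  }
  expect_equal(st$Ve, p$A / p$a, tolerance = 0.01)
  expect_equal(st$Vi, p$B / p$b, tolerance = 0.01)
  # zero drive from a zero state stays exactly zero
  st0 <- mass_state(params = p)
  st0 <- impulse_response_step(st0, 0, 0, p, dt)
  expect_identical(c(st0$Ve, st0$Vi, st0$ze, st0$zi), rep(0, 4))
  # unit-area impulse: peak at t = 1/a with height A/e
  st <- mass_state(params = p)
  st <- impulse_response_step(st, drive_e = 1 / dt, drive_i = 0, p, dt)
  traj <- numeric(60)
  traj[1] <- st$Ve
  for (i in 2:60) {
    st <- impulse_response_step(st, 0, 0, p, dt)
    traj[i] <- st$Ve
  }
  expect_equal(which.max(traj) * dt, 1 / p$a, tolerance = dt / (1 / p$a) + 1e-9)
  expect_equal(max(traj), p$A / exp(1), tolerance = 0.01)
})

test_that("coarse filter step matches a 100x finer reference integration", {
  # drive sampled at each scheme's step midpoint, so both integrations
  # approximate the same continuous drive without a half-step offset
  p <- mass_params()
  dt <- 1e-3
  drive <- function(t) 50 * (1 + sin(2 * pi * 5 * t))
  coarse <- mass_state(params = p)
  for (i in seq_len(1000)) {
    coarse <- impulse_response_step(coarse, drive((i - 0.5) * dt), 0, p, dt)
  }
  fine <- mass_state(params = p)
  dtf <- dt / 100
  for (i in seq_len(100000)) {
    fine <- impulse_response_step(fine, drive((i - 0.5) * dtf), 0, p, dtf)
  }
  expect_equal(coarse$Ve, fine$Ve, tolerance = 0.005)
})

test_that("a quiescent mass stays at its fixed point and noise is reproducible", {
  p <- mass_params(P_mean = 0, P_sd = 0)
  # settle to the zero-input fixed point, then check invariance
  st <- mass_state(params = p)
  for (i in seq_len(5000)) st <- step_mass(st, external = 0, p, dt = 1e-3)
  ref <- st
  for (i in seq_len(100)) st <- step_mass(st, external = 0, p, dt = 1e-3)
  expect_equal(st$Ve, ref$Ve, tolerance = 1e-9)
  expect_equal(st$Vi, ref$Vi, tolerance = 1e-9)
  # identical rng draws give bit-identical trajectories
  pn <- mass_params()
  run_one <- function() {
    set.seed(42)
    s <- mass_state(Ve = 5, Vi = 3, params = pn)
    out <- numeric(200)
    for (i in seq_len(200)) {
      s <- step_mass(s, 0, pn, 1e-3, rng_draw = rnorm(1))
      out[i] <- s$Ve
    }
    out
  }
  expect_identical(run_one(), run_one())
})

test_that("R single-mass stepper and compiled network engine agree", {
  p <- mass_params()
  conn <- one_node_connectome()
  n_steps <- 1000
  set.seed(9)
  noise <- matrix(pmax(0, rnorm(n_steps, p$P_mean, p$P_sd)), ncol = 1)
  sim <- run_cycle(conn, states = init_network_states(conn, p),
                   params = p, duration = 1, dt = 1e-3, fs = 1000,
                   transient = 0, noise = noise)
  s <- mass_state(Ve = p$Vd1, Vi = p$Vd2, params = p)
  r_traj <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    s <- step_mass(s, external = 0, p, dt = 1e-3,
                   rng_draw = (noise[i, 1] - p$P_mean) / p$P_sd)
    r_traj[i] <- s$Ve
  }
  expect_equal(unname(sim$output$signals[, 1]), r_traj, tolerance = 1e-12)
})

test_that("an uncoupled mass oscillates in the alpha band with bounded rates", {
  conn <- one_node_connectome()
  p <- mass_params()
  out <- settle_and_run(conn, p, n_settle = 1, seed = 3)
  pk <- peak_frequency(out$signals[, 1], out$fs)
  expect_gte(pk, 8)
  expect_lte(pk, 13)
  expect_true(all(out$spike_density >= 0 & out$spike_density <= p$q))
})
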