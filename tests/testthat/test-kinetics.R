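test_that("rate laws follow the exponential voltage dependence", {
  a <- rate_law(0.1219, 0.6232)
  expect_equal(rate_at(a, 0), 0.1219)
  expect_equal(rate_at(a, 50, VT), 0.1219 * exp(0.6232 * 50 / VT))
  # zero gating charge: voltage-independent
  flat <- rate_law(2.5, 0)
  expect_equal(rate_at(flat, c(-120, 0, 50)), rep(2.5, 3))
  expect_error(rate_at(a, NA))
})

test_that("ZHA A generator reproduces the symbolic 5x5 tetramer matrix", {
  m <- build_zha_a()
  for (V in c(-120, -60, 0, 25, 50)) {
    al <- 0.1219 * exp(0.6232 * V / VT)
    be <- 0.0342 * exp(-0.0207 * V / VT)
    expected <- matrix(0, 5, 5)
    fwd_mult <- c(4, 3, 2, 1); bwd_mult <- c(1, 2, 3, 4)
    for (i in 1:4) {
      expected[i + 1, i] <- fwd_mult[i] * al
      expected[i, i + 1] <- bwd_mult[i] * be
    }
    diag(expected) <- -colSums(expected)
    W <- transition_matrix(m, V, VT)
    expect_equal(unname(W), expected, tolerance = 1e-12)
  }
})

test_that("BPS generator is tridiagonal with the published rate pattern", {
  m <- build_bps()
  p <- shaker_parameters()$bps
  fwd_names <- c("alpha0", "alpha1", "alpha1", "alpha1", "alpha2", "alpha3", "alpha4")
  bwd_names <- c("beta0", "beta1", "beta1", "beta1", "beta2", "beta3", "beta4")
  for (V in c(-120, -60, 0, 25, 50)) {
    expected <- matrix(0, 8, 8)
    for (i in 1:7) {
      f <- p$rates[[fwd_names[i]]]
      b <- p$rates[[bwd_names[i]]]
      expected[i + 1, i] <- f$amplitude * exp(f$charge * V / VT)
      expected[i, i + 1] <- b$amplitude * exp(-b$charge * V / VT)
    }
    diag(expected) <- -colSums(expected)
    W <- transition_matrix(m, V, VT)
    expect_equal(unname(W), expected, tolerance = 1e-12)
    # strictly tridiagonal
    expect_true(all(W[abs(row(W) - col(W)) > 1] == 0))
  }
})

test_that("generator columns sum to zero for all models and voltages", {
  for (m in all_shaker_models()) {
    for (V in c(-120, 0, 50)) {
      W <- transition_matrix(m, V, VT)
      expect_lt(max(abs(colSums(W))), 1e-12 * max(abs(W)))
    }
  }
})

test_that("equilibrium matches the two-state closed form and kills the generator", {
  toy <- two_state_model(0.5, 1, 0.2, -0.5)
  for (V in c(-60, 0, 30)) {
    al <- 0.5 * exp(V / VT); be <- 0.2 * exp(-0.5 * V / VT)
    eq <- equilibrium(toy, V, VT)
    expect_equal(unname(eq["O"]), al / (al + be), tolerance = 1e-12)
  }
  for (m in all_shaker_models()) {
    for (V in c(-90, 0, 42)) {
      eq <- equilibrium(m, V, VT)
      expect_equal(sum(eq), 1, tolerance = 1e-12)
      expect_true(all(eq >= 0))
      W <- transition_matrix(m, V, VT)
      expect_lt(max(abs(W %*% eq)), 1e-10)
    }
  }
})

test_that("ZHA A equilibrium equals the independent subunit binomial", {
  # four independent two-state subunits: P(k activated) is binomial in the
  # single-subunit open probability - an exact closed form
  m <- build_zha_a()
  for (V in c(-120, -90, 0, 42)) {
    al <- 0.1219 * exp(0.6232 * V / VT)
    be <- 0.0342 * exp(-0.0207 * V / VT)
    p1 <- al / (al + be)
    expected <- dbinom(0:4, 4, p1)
    expect_equal(unname(equilibrium(m, V, VT)), expected, tolerance = 1e-10)
  }
})

test_that("linear-chain models satisfy detailed balance at stationarity", {
  for (m in all_shaker_models()[c("zha_a", "bps")]) {
    for (V in c(-90, 0, 42)) {
      eq <- equilibrium(m, V, VT)
      tr <- m$transitions
      rates <- tr$multiplicity * tr$scale * tr$amplitude * exp(tr$charge * V / VT)
      flux <- rates * eq[tr$from]
      net <- flux - flux[match(paste(tr$to, tr$from), paste(tr$from, tr$to))]
      expect_lt(max(abs(net)), 1e-10)
    }
  }
})

test_that("propagation matches the two-state closed-form relaxation", {
  toy <- two_state_model(0.8, 0.9, 0.3, -0.4)
  V1 <- -80; V2 <- 20; dt <- 0.01; n <- 2000
  p0 <- equilibrium(toy, V1, VT)
  wf <- voltage_waveform(rep(V2, n), dt = dt)
  traj <- propagate(toy, wf, p0, VT)
  al <- 0.8 * exp(0.9 * V2 / VT); be <- 0.3 * exp(-0.4 * V2 / VT)
  p_inf <- al / (al + be)
  t <- (seq_len(n) - 1L) * dt
  expected <- p_inf + (p0["O"] - p_inf) * exp(-(al + be) * t)
  expect_equal(unname(traj["O", ]), unname(expected), tolerance = 1e-8)
})

test_that("long constant-voltage propagation relaxes to equilibrium", {
  m <- build_zha_d()
  p0 <- equilibrium(m, -90, VT)
  wf <- voltage_waveform(rep(0, 4000), dt = 0.05)  # 200 ms
  traj <- propagate(m, wf, p0, VT)
  eq <- equilibrium(m, 0, VT)
  expect_lt(0.5 * sum(abs(traj[, ncol(traj)] - eq)), 1e-6)
})

test_that("probability is conserved over 1e4 fluctuating steps for all models", {
  set.seed(42)
  V <- pmin(50, pmax(-120,
    -50 + 90 * sin(seq(0, 40 * pi, length.out = 1e4)) + rnorm(1e4, 0, 5)))
  wf <- voltage_waveform(V, dt = 0.01)
  for (m in all_shaker_models()) {
    p0 <- equilibrium(m, -90, VT)
    traj <- propagate(m, wf, p0, VT, quantum = 0.05)
    expect_lt(max(abs(colSums(traj) - 1)), 1e-9)
    expect_true(all(traj >= -1e-12))
  }
})

test_that("the single-step propagator is a stochastic matrix", {
  for (m in all_shaker_models()) {
    for (V in c(-120, -45, 0, 50)) {
      P <- waveclamp:::cpp_expm(transition_matrix(m, V, VT), 0.02)
      expect_true(all(P >= -1e-12))
      expect_lt(max(abs(colSums(P) - 1)), 1e-10)
    }
  }
})

test_that("halving dt leaves piecewise-constant responses unchanged", {
  m <- build_bps()
  segs <- list(step_segment(-90, 2), step_segment(42, 10), step_segment(-60, 4))
  sim1 <- simulate_current(m, steps_to_waveform(segs, dt = 0.02))
  sim2 <- simulate_current(m, steps_to_waveform(segs, dt = 0.01))
  shared <- sim2$current$samples[seq(1, length(sim2$current$samples), by = 2)]
  rel_rms <- sqrt(mean((sim1$current$samples - shared)^2)) /
    sqrt(mean(shared^2))
  expect_lt(rel_rms, 1e-4)
})

test_that("Ohm's-law current has the expected zeros and scale", {
  m <- build_zha_a()
  wf <- voltage_waveform(rep(0, 10), dt = 0.01)
  # all probability in the open state
  traj_open <- matrix(0, 5, 10); traj_open[5, ] <- 1
  i <- ohmic_current(m, wf, traj_open, v_rev = -90)
  expect_equal(i$samples, rep(0.9717 * 0.07696 * 90, 10))
  # no open probability -> zero current
  traj_closed <- matrix(0, 5, 10); traj_closed[1, ] <- 1
  expect_equal(ohmic_current(m, wf, traj_closed, v_rev = -90)$samples, rep(0, 10))
  # V = Vr -> zero driving force
  wf_r <- voltage_waveform(rep(-90, 10), dt = 0.01)
  expect_equal(ohmic_current(m, wf_r, traj_open, v_rev = -90)$samples, rep(0, 10))
})

test_that("simulation starts flat at holding equilibrium and activates on a step", {
  m <- build_zha_a()
  hold <- steps_to_waveform(list(step_segment(-90, 5)), dt = 0.01)
  sim <- simulate_current(m, hold, v_hold = -90, v_rev = -90)
  expect_lt(max(abs(sim$current$samples)), 1e-12)   # V = Vr at hold
  expect_lt(max(abs(sim$open_probability - sim$open_probability[1])), 1e-9)

  step <- steps_to_waveform(list(step_segment(42, 30)), dt = 0.01)
  sim2 <- simulate_current(m, step, v_hold = -90, v_rev = -90)
  op <- sim2$open_probability
  expect_true(all(diff(op) > -1e-12))               # monotone sigmoid rise
  eq_open <- unname(equilibrium(m, 42, VT)["O"])
  expect_equal(op[length(op)], eq_open, tolerance = 1e-3)
})

test_that("distinct gating models produce distinct currents under one step", {
  wf <- steps_to_waveform(list(step_segment(-90, 1), step_segment(42, 15)),
                          dt = 0.02)
  sim_d <- simulate_current(build_zha_d(), wf)
  sim_s <- simulate_current(build_ss(), wf)
  expect_gt(chi2_divergence(sim_d$current, sim_s$current), 0)
})

test_that("propagate validates its inputs", {
  m <- build_zha_a()
  wf <- voltage_waveform(rep(0, 5), dt = 0.01)
  expect_error(propagate(m, wf, c(1, 0, 0)), "length")
  expect_error(propagate(m, wf, c(0.5, 0.5, 0.5, 0, 0)), "probability")
})
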