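test_that("low-pass filters relax to the rate with their nominal timescale", {
  ps <- plasticity_state(4, tau_P = 50, tau_D = 50, tau_x = 20)
  phi <- nonlinearity("tanh")
  x <- c(0.5, -1, 2, 0)

  # constant input held for 10 tau: filter at its fixed point
  for (k in 1:5000) ps <- update_filters(ps, x, phi, 0.1)
  expect_equal(ps$yP, tanh(x), tolerance = 1e-3)
  expect_equal(ps$xbar, x, tolerance = 1e-3)

  # zero input keeps a zeroed filter at zero
  ps0 <- plasticity_state(4)
  ps0 <- update_filters(ps0, rep(0, 4), phi, 0.1)
  expect_identical(ps0$yP, rep(0, 4))

  # step response: fitted exponential timescale within 2% of tau
  ps <- plasticity_state(1, tau_P = 50)
  xs <- 1
  resid <- numeric(2000)
  for (k in 1:2000) {
    ps <- update_filters(ps, xs, phi, 0.1)
    resid[k] <- tanh(xs) - ps$yP
  }
  fit <- stats::lm(log(resid) ~ seq_along(resid))
  tau_hat <- -0.1 / stats::coef(fit)[2]
  expect_equal(unname(tau_hat), 50, tolerance = 0.02)
})

test_that("synaptic noise has the stated per-entry statistics", {
  st <- seed_streams(10)
  N <- 32
  draws <- replicate(100, noise_term(st, N))
  expect_equal(mean(draws), 0, tolerance = 5e-4)
  expect_equal(stats::var(as.vector(draws)), 1 / N, tolerance = 0.02)
  # half-normal mean E|xi| = sqrt(2/(pi N))
  expect_equal(mean(abs(draws)), sqrt(2 / (pi * N)), tolerance = 0.01)

  # a fresh draw every call
  expect_false(identical(noise_term(st, N), noise_term(st, N)))

  # mask with exactly half the entries zero
  mask <- matrix(rep(c(0, 1), length.out = N * N), N, N)
  xi <- noise_term(st, N, mask)
  expect_identical(sum(xi == 0), sum(mask == 0))
})

test_that("dissipation gives exponential weight decay at rate eta*beta", {
  expect_equal(dissipation_term(diag(4), beta = 0.1), -0.1 * diag(4))

  st <- seed_streams(3)
  W <- matrix(stream_rnorm(st, "init_W", 16 * 16, sd = 0.25), 16, 16)
  expect_equal(dissipation_term(W, 0.3), ref_dissipation(W, 0.3))

  # closed form: W(t) = W0 (1 - dt*eta*beta)^k, every eigenvalue decays at
  # the same fitted rate eta*beta
  eta <- 0.01; beta <- 0.1; dt <- 0.1
  snaps <- list(W)
  Wk <- W
  for (s in 1:20) {
    for (k in 1:500) Wk <- step_weights(Wk, 0, dissipation_term(Wk, beta), eta, dt)
    snaps[[s + 1]] <- Wk
  }
  tr <- track_eigenvalues(snaps, times = seq(0, 1000, by = 50))
  lam0 <- Mod(tr$eigvals[1, ])
  keep <- lam0 > 1e-3
  rates <- apply(tr$eigvals[, keep, drop = FALSE], 2, function(lam) {
    -stats::coef(stats::lm(log(Mod(lam)) ~ tr$times))[2]
  })
  expect_true(all(abs(rates - eta * beta) < 0.01 * eta * beta))
})

test_that("rate-control and decorrelation terms match scalar references", {
  st <- seed_streams(8)
  N <- 16
  x <- stream_rnorm(st, "init_x", N)
  xbar <- stream_rnorm(st, "init_x", N)
  W <- matrix(stream_rnorm(st, "init_W", N * N), N, N)
  phi0 <- stream_runif(st, "patterns", N, -1, 1)

  expect_equal(rate_control_term(x, W, phi0), ref_rate_control(x, W, phi0))
  expect_equal(decorrelation_term(x, xbar), ref_decorrelation(x, xbar))

  # set-point identities
  x_at_target <- atanh(phi0 * 0.99)
  expect_equal(rate_control_term(x_at_target, W, phi0 * 0.99),
               matrix(0, N, N), tolerance = 1e-12)
  expect_equal(rate_control_term(rep(0, N), W, phi0), matrix(0, N, N))
  expect_equal(decorrelation_term(rep(0, N), rep(0, N)), diag(N))
  expect_equal(decorrelation_term(x, x), diag(N))
})

test_that("the STDP operator matches its reference and is anti-symmetric for the symmetric kernel", {
  st <- seed_streams(9)
  N <- 16
  phi_x <- tanh(stream_rnorm(st, "init_x", N))
  ps <- plasticity_state(N)
  ps$yP <- stream_rnorm(st, "init_x", N)
  ps$yD <- stream_rnorm(st, "init_x", N)

  general <- stdp_config(a_P = 1.3, a_D = -0.4, tau_P = 30, tau_D = 80)
  expect_false(is_antisymmetric_stdp(general))
  expect_equal(stdp_term(phi_x, ps, general),
               ref_stdp(phi_x, ps$yP, ps$yD, 1.3, -0.4))

  anti <- stdp_config(a_P = 2, a_D = -2)
  expect_true(is_antisymmetric_stdp(anti))
  ps$yD <- ps$yP
  dL <- stdp_term(phi_x, ps, anti)
  expect_equal(dL + t(dL), matrix(0, N, N))
  expect_equal(dL, 2 * (tcrossprod(phi_x, ps$yP) - tcrossprod(ps$yP, phi_x)))

  # stationary activity (y = phi) nullifies the anti-symmetric operator
  ps$yP <- phi_x; ps$yD <- phi_x
  expect_equal(stdp_term(phi_x, ps, anti), matrix(0, N, N), tolerance = 1e-14)
})

test_that("weight stepping respects masks and anti-symmetric closure", {
  st <- seed_streams(12)
  N <- 8
  W <- matrix(stream_rnorm(st, "init_W", N * N), N, N)
  expect_identical(step_weights(W, 0, 0, 0.01, 0.1), W)

  A <- W - t(W)
  dL <- {
    a <- stream_rnorm(st, "init_x", N); b <- stream_rnorm(st, "init_x", N)
    tcrossprod(a, b) - tcrossprod(b, a)
  }
  A2 <- step_weights(A, dL, 0, 0.5, 0.1)
  expect_equal(A2 + t(A2), matrix(0, N, N))

  mask <- matrix(stream_runif(st, "patterns", N * N) < 0.5, N, N) * 1
  Wm <- step_weights(W * mask, dL, matrix(1, N, N), 0.5, 0.1, mask = mask)
  expect_true(all(Wm[mask == 0] == 0))
})

test_that("noise-driven weights follow the random-walk / OU variance laws", {
  st <- seed_streams(21)
  N <- 24; eta <- 0.5; dt <- 0.1
  # pure random walk: per-entry variance grows linearly at (dt*eta)^2/N per step
  W <- matrix(0, N, N)
  nstep <- 400
  for (k in 1:nstep) W <- step_weights(W, 0, noise_term(st, N), eta, dt)
  expect_equal(stats::var(as.vector(W)), nstep * (dt * eta)^2 / N, tolerance = 0.1)

  # with dissipation: stationary OU variance (dt*eta)^2/N / (1 - (1 - dt*eta*beta)^2)
  beta <- 0.5
  W <- matrix(0, N, N)
  a <- 1 - dt * eta * beta
  for (k in 1:2000) W <- step_weights(W, 0, dissipation_term(W, beta) + noise_term(st, N), eta, dt)
  v_inf <- (dt * eta)^2 / N / (1 - a^2)
  expect_equal(stats::var(as.vector(W)), v_inf, tolerance = 0.05)
})

test_that("anti-symmetric learning never changes the symmetric part of W", {
  st <- seed_streams(30)
  cfg <- sim_config(N = 24, seed = 30, g = 0.5)
  W0 <- as_weight_matrix(random_connectivity(cfg, st))
  it <- sample_memory(st, 24)
  stim <- ou_stimulus(it, 0, 20, cfg$dt, st, amplitude = 10)
  run <- simulate_network(cfg, W0, duration = 20, streams = st, input_fn = stim,
                          hcfg = homeostasis_config("none", noise_on = FALSE),
                          stdp = stdp_config(a_P = 5, a_D = -5),
                          record_every = 0, snap_every = 0)
  S0 <- sym_antisym_decompose(W0)$S
  S1 <- sym_antisym_decompose(run$W)$S
  expect_equal(S1, S0, tolerance = 1e-12)
  # and the anti-symmetric part did change (learning happened)
  expect_gt(max(abs(sym_antisym_decompose(run$W)$A - sym_antisym_decompose(W0)$A)), 1e-6)
})

test_that("fluctuation term assembles rule + noise and honors the mask", {
  st <- seed_streams(40)
  cfg <- sim_config(N = 12, seed = 40)
  hcfg <- homeostasis_config("dissipation", beta = 0.2, noise_on = FALSE)
  W <- matrix(1, 12, 12)
  ps <- plasticity_state(12)
  f <- fluctuation_term(rep(0, 12), W, ps, hcfg, cfg, st)
  expect_equal(f$total, -0.2 * W)
  expect_equal(f$noise, matrix(0, 12, 12))

  mask <- diag(12)
  hcfg2 <- homeostasis_config("decorrelation", noise_on = TRUE)
  f2 <- fluctuation_term(rep(0.5, 12), W, ps, hcfg2, cfg, st, mask = mask)
  expect_true(all(f2$total[mask == 0] == 0))
})
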