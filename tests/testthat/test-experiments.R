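test_that("dissipation erosion with noise off follows the closed form", {
  r <- erosion_experiment("dissipation", N = 32, seed = 1, horizon = 800,
                          burn_in = 50, noise_on = FALSE)
  # both embeddings decay at the same fitted rate eta*beta = 1e-3
  expect_equal(r$decay_rate_real, 1e-3, tolerance = 0.01)
  expect_equal(r$decay_rate_imag, 1e-3, tolerance = 0.01)
  expect_equal(r$decay_rate_real / r$decay_rate_imag, 1, tolerance = 0.02)
  expect_false(r$blowup_real || r$blowup_imag)
  # half-life of exponential decay: ln 2 / rate, measured against baseline 0-ish
  expect_gt(r$halflife_real, 0)
})

test_that("paired erosion branches consume an identical noise realization", {
  # the pairing contract is carried by clone_streams: both branches replay
  # the same noise stream after the shared burn-in
  s <- seed_streams(5)
  stream_rnorm(s, "noise", 64)   # burn-in consumption
  b1 <- clone_streams(s)
  b2 <- clone_streams(s)
  expect_identical(noise_term(b1, 16), noise_term(b2, 16))
})

test_that("erosion reports carry the embedding geometry", {
  r <- erosion_experiment("dissipation", N = 24, seed = 2, horizon = 100,
                          burn_in = 20, noise_on = FALSE)
  expect_equal(r$a_embed, 1.5 * r$bulk_radius)
  expect_equal(r$amp_real[1], r$a_embed + 0, tolerance = 0.2)
  expect_equal(r$amp_imag[1], r$a_embed, tolerance = 0.05)
  expect_equal(r$times[1], 0)
})

test_that("sparsity: a density-1 mask reproduces the dense run exactly", {
  r_dense <- erosion_experiment("dissipation", N = 24, seed = 3, horizon = 100,
                                burn_in = 20, noise_on = FALSE, density = 1)
  sw <- sparsity_sweep(densities = c(1, 0.5), N = 24, seed = 3, rule = "dissipation",
                       horizon = 100, burn_in = 20, noise_on = FALSE)
  expect_equal(sw$reports[[1]]$amp_imag, r_dense$amp_imag)
  # masking dilutes the realized embedded amplitude
  expect_lt(sw$imag_amplitude[2], sw$imag_amplitude[1])
})

test_that("run archives round-trip through the directory format", {
  dir <- withr::local_tempdir()
  r <- erosion_experiment("dissipation", N = 16, seed = 4, horizon = 60,
                          burn_in = 10, noise_on = FALSE)
  write_run(r, dir)
  back <- read_run(dir)
  expect_equal(back$report$halflife_real, r$halflife_real)
  expect_equal(back$report$rule, "dissipation")
  expect_equal(back$report$ratio, r$ratio)
  expect_equal(back$report$amp_imag, r$amp_imag, tolerance = 1e-12)
  expect_error(read_run(file.path(dir, "missing")), "missing artifact")
})

test_that("trajectory and spectrum CSV writers emit readable tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  cfg <- sim_config(N = 4, dt = 0.1)
  traj <- run_trajectory(c(1, 0, 0, 0), matrix(0, 4, 4), NULL, 1, cfg)
  write_trajectory_csv(traj, f)
  tab <- utils::read.csv(f)
  expect_equal(dim(tab), c(10L, 5L))
  expect_equal(tab$time, traj$times)
  expect_equal(tab$x_0, traj$X[, 1], tolerance = 1e-15)

  f2 <- withr::local_tempfile(fileext = ".csv")
  tr <- track_eigenvalues(list(diag(3), 2 * diag(3)))
  write_spectrum_csv(tr, f2)
  tab2 <- utils::read.csv(f2)
  expect_equal(nrow(tab2), 6L)
  expect_equal(sort(unique(tab2$re)), c(1, 2))
})

test_that("capacity report structure is sound on a tiny instance", {
  cap <- capacity_experiment(N_values = 64, loads = c(0.04, 0.3), trials = 3,
                             steps = 40, seed = 2)
  expect_equal(length(cap$critical_antisym), 1L)
  expect_true(all(cap$results[[1]]$hopfield$rates %in% seq(0, 1, by = 1/3)))
  expect_gte(cap$critical_hopfield[1], 0.04)
  # Hopfield retrieves at trivial load and fails far above capacity
  expect_equal(cap$results[[1]]$hopfield$rates[1], 1)
  expect_lt(cap$results[[1]]$hopfield$rates[2], 0.5)
})

test_that("the learning report is reproducible from its seed", {
  r1 <- learning_experiment(N = 32, seed = 6, durations = 30, second_plane = FALSE)
  r2 <- learning_experiment(N = 32, seed = 6, durations = 30, second_plane = FALSE)
  expect_identical(r1$strengths, r2$strengths)
  expect_identical(r1$top_overlaps, r2$top_overlaps)
})
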