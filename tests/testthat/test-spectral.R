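test_that("sym/antisym decomposition reconstructs W exactly", {
  st <- seed_streams(2)
  W <- matrix(stream_rnorm(st, "init_W", 64), 8, 8)
  d <- sym_antisym_decompose(W)
  expect_equal(d$S + d$A, W)
  expect_equal(d$S, t(d$S))
  expect_equal(d$A, -t(d$A))
  expect_equal(sym_antisym_decompose(d$S)$A, matrix(0, 8, 8))
  it <- orth_pair(8)
  expect_equal(sym_antisym_decompose(tcrossprod(it$u, it$v) - tcrossprod(it$v, it$u))$S,
               matrix(0, 8, 8))
})

test_that("plane projection is the stated linear functional", {
  N <- 100
  it <- orth_pair(N)
  p <- project_onto_plane(sqrt(N) * it$u, it)
  expect_equal(unname(p["p_u"]), 1)
  expect_equal(unname(p["p_v"]), 0, tolerance = 1e-12)
  expect_equal(unname(p["r"]), 1)

  st <- seed_streams(3)
  x <- stream_rnorm(st, "init_x", N); y <- stream_rnorm(st, "init_x", N)
  px <- project_onto_plane(x, it); py <- project_onto_plane(y, it)
  pz <- project_onto_plane(2 * x - 3 * y, it)
  expect_equal(unname(pz["p_u"]), unname(2 * px["p_u"] - 3 * py["p_u"]))

  z <- x - sum(x * it$u) * it$u - sum(x * it$v) * it$v
  expect_equal(unname(project_onto_plane(z, it)[c("p_u", "p_v", "r")]),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("plane overlap is basis-invariant, symmetric and normalized", {
  N <- 64
  st <- seed_streams(5)
  q <- qr.Q(qr(matrix(stream_rnorm(st, "patterns", N * 4), N, 4)))
  u1 <- q[, 1]; v1 <- q[, 2]; u2 <- q[, 3]; v2 <- q[, 4]

  same <- plane_overlap(u1, v1, u1, v1)
  expect_equal(same$raw, sqrt(2), tolerance = 1e-12)
  expect_equal(same$normalized, 1, tolerance = 1e-12)
  expect_equal(plane_overlap(u1, v1, u2, v2)$raw, 0, tolerance = 1e-12)

  # in-plane rotation of the second basis leaves the overlap unchanged
  for (k in 1:5) {
    th <- stream_runif(st, "trials", 1, 0, 2 * pi)
    u2r <- cos(th) * u1 + sin(th) * v1
    v2r <- -sin(th) * u1 + cos(th) * v1
    expect_equal(plane_overlap(u1, v1, u2r, v2r)$raw, sqrt(2), tolerance = 1e-10)
  }

  # symmetry in the two planes, for partially overlapping ones
  w <- (v1 + u2) / sqrt(2)
  o12 <- plane_overlap(u1, v1, u1, w)
  o21 <- plane_overlap(u1, w, u1, v1)
  expect_equal(o12$raw, o21$raw, tolerance = 1e-10)
  expect_error(plane_overlap(rep(0, N), v1, u2, v2))
})

test_that("the assignment solver is exactly optimal on small instances", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- perms(n - 1)
    do.call(rbind, lapply(1:n, function(i) cbind(i, sub + (sub >= i))))
  }
  st <- seed_streams(6)
  for (trial in 1:30) {
    n <- 2 + trial %% 5
    cost <- matrix(stream_runif(st, "trials", n * n), n, n)
    p <- solve_assignment(cost)
    expect_true(all(sort(p) == 1:n))
    best <- min(apply(perms(n), 1, function(pp) sum(cost[cbind(1:n, pp)])))
    expect_equal(sum(cost[cbind(1:n, p)]), best, tolerance = 1e-12)
  }
})

test_that("eigenvalue tracking follows a slowly rotating family without swaps", {
  # constant sequence: trajectories constant
  st <- seed_streams(7)
  W <- matrix(stream_rnorm(st, "init_W", 36), 6, 6)
  tr <- track_eigenvalues(list(W, W, W))
  expect_equal(tr$eigvals[1, ], tr$eigvals[3, ])

  # rotation generator scaled by a slowly varying s(t): tracked pair = +/- i s
  N <- 6
  it <- orth_pair(N, seed = 8)
  s_k <- seq(0.5, 3, length.out = 40)
  snaps <- lapply(s_k, function(s) s * (tcrossprod(it$u, it$v) - tcrossprod(it$v, it$u)))
  tr2 <- track_eigenvalues(snaps)
  j_pos <- which.max(Im(tr2$eigvals[1, ]))
  expect_equal(Im(tr2$eigvals[, j_pos]), s_k, tolerance = 1e-8)
  expect_equal(Re(tr2$eigvals[, j_pos]), rep(0, 40), tolerance = 1e-8)

  # spectrum set equality at every snapshot
  for (k in c(1, 20, 40)) {
    expect_equal(sort(Mod(tr2$eigvals[k, ])),
                 sort(Mod(eigen(snaps[[k]], only.values = TRUE)$values)),
                 tolerance = 1e-8)
  }

  # conjugate pairing preserved along trajectories of a real family
  expect_true(all(abs(apply(tr2$eigvals, 1, function(z) sum(Im(z)))) < 1e-8))
})

test_that("crossing trajectories with distinct eigenvectors are not swapped", {
  # two rotation blocks on disjoint coordinate planes; their imaginary parts
  # cross as one grows and the other shrinks
  a_k <- seq(0.5, 2.0, length.out = 31)
  b_k <- seq(2.0, 0.5, length.out = 31)
  blk <- function(a, b) {
    W <- matrix(0, 4, 4)
    W[1, 2] <- a; W[2, 1] <- -a
    W[3, 4] <- b; W[4, 3] <- -b
    W
  }
  snaps <- lapply(1:31, function(k) blk(a_k[k], b_k[k]))
  tr <- track_eigenvalues(snaps)
  # the trajectory that starts at +0.5i must grow monotonically through the
  # crossing at 1.25 and end at +2i (value-only matching would swap there)
  j <- which.min(abs(tr$eigvals[1, ] - 0.5i))
  traj <- Im(tr$eigvals[, j])
  expect_equal(traj, a_k, tolerance = 1e-8)
})

test_that("memory eigenpair extraction identifies embedded planes", {
  N <- 64
  it <- orth_pair(N, seed = 9)
  item <- memory_item(it$u, it$v, rho = 4)
  W <- embed_imaginary(matrix(0, N, N), item)
  mp <- memory_eigenpair(W, item)
  expect_false(mp$absent)
  expect_equal(mp$lambda, 0 + 4i, tolerance = 1e-8)
  expect_equal(mp$overlap, 1, tolerance = 1e-8)

  # outlier above a random bulk: strong |Im| and high overlap
  st <- seed_streams(9)
  cfg <- sim_config(N = N, seed = 9, g = 1)
  Wb <- embed_imaginary(as_weight_matrix(random_connectivity(cfg, st)), item)
  mpb <- memory_eigenpair(Wb, item)
  expect_gt(abs(Im(mpb$lambda)), 3)
  expect_gt(mpb$overlap, 0.9)
  top <- top_imaginary_eigenpair(Wb)
  expect_equal(top$lambda, mpb$lambda)

  # symmetric matrices have no conjugate pair
  S <- tcrossprod(matrix(stream_rnorm(st, "init_W", N * 3), N, 3))
  expect_true(memory_eigenpair(S, item)$absent)
  expect_true(top_imaginary_eigenpair(S)$absent)
})

test_that("dominant frequency recovers sinusoids and flags flat series", {
  t <- seq(0, 100, by = 0.1)
  f0 <- 0.23
  f_hat <- dominant_frequency(sin(2 * pi * f0 * t), 0.1)
  expect_equal(f_hat, f0, tolerance = 1 / (length(t) * 0.1))

  flat <- rep(1.3, 128)
  out <- dominant_frequency(flat, 0.1)
  expect_true(is.na(out))
  expect_true(attr(out, "no_peak"))
  expect_error(dominant_frequency(rep(1, 10), 0.1))
})

test_that("retrieval oscillation frequency increases with memory strength", {
  N <- 256
  it <- orth_pair(N, seed = 10)
  cfg <- sim_config(N = N, dt = 0.1)
  freqs <- sapply(c(4, 8), function(rho) {
    W <- embed_imaginary(matrix(0, N, N), memory_item(it$u, it$v, rho = rho, gamma = 1.5))
    traj <- run_trajectory(sqrt(N) * it$u, W, NULL, 60, cfg,
                           project_items = list(it))
    dominant_frequency(traj$proj[[1]][201:600, "p_u"], 0.1)
  })
  expect_gt(freqs[2], freqs[1])
})
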