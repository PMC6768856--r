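test_that("sampled memory patterns have Gaussian 1/N statistics", {
  st <- seed_streams(1)
  it <- sample_memory(st, 4096)
  expect_lt(abs(sum(it$u * it$v)), 0.1)
  expect_true(sqrt(sum(it$u^2)) > 0.9 && sqrt(sum(it$u^2)) < 1.1)

  # deterministic under the seed
  st2 <- seed_streams(1)
  it2 <- sample_memory(st2, 4096)
  expect_identical(it$u, it2$u)

  # expected inner product vanishes over resamples
  st3 <- seed_streams(2)
  dots <- replicate(1000, { m <- sample_memory(st3, 64); sum(m$u * m$v) })
  expect_lt(abs(mean(dots)), 3 / sqrt(64 * 1000) * 5)
})

test_that("real embedding is a symmetric rank-1 projector on u", {
  it <- orth_pair(64)
  W <- embed_real(matrix(0, 64, 64), it$u)
  ev <- eigen(W, symmetric = TRUE)
  expect_equal(sort(ev$values, decreasing = TRUE)[1], 1, tolerance = 1e-12)
  expect_equal(sum(abs(ev$values) > 1e-10), 1L)
  expect_equal(W, t(W))
  expect_gt(abs(sum(ev$vectors[, 1] * it$u)), 0.99)
})

test_that("imaginary embedding realizes the gamma +/- i rho eigenvalue pair", {
  it <- orth_pair(32)
  W0 <- embed_imaginary(matrix(0, 32, 32), memory_item(it$u, it$v, rho = 4))
  ev <- eigen(W0, only.values = TRUE)$values
  ims <- sort(Im(ev), decreasing = TRUE)
  expect_equal(ims[1], 4, tolerance = 1e-10)
  expect_equal(sort(Mod(ev), decreasing = TRUE)[3], 0, tolerance = 1e-10)
  expect_equal(W0 + t(W0), matrix(0, 32, 32), tolerance = 1e-12)

  Wg <- embed_imaginary(matrix(0, 32, 32), memory_item(it$u, it$v, rho = 4, gamma = 1.5))
  evg <- eigen(Wg, only.values = TRUE)$values
  top <- evg[which.max(Im(evg))]
  expect_equal(Re(top), 1.5, tolerance = 1e-10)
  expect_equal(Im(top), 4, tolerance = 1e-10)

  # symmetric part untouched by the gamma = 0 embedding
  st <- seed_streams(4)
  Wr <- matrix(stream_rnorm(st, "init_W", 32 * 32), 32, 32)
  We <- embed_imaginary(Wr, memory_item(it$u, it$v, rho = 2))
  expect_equal(sym_antisym_decompose(We)$S, sym_antisym_decompose(Wr)$S, tolerance = 1e-12)
})

test_that("a memory bank reproduces per-item embeddings and rank 2M", {
  N <- 48
  st <- seed_streams(6)
  i1 <- orthonormalize_item(sample_memory(st, N))
  # single item bank equals direct embedding
  b1 <- memory_bank(list(memory_item(i1$u, i1$v, rho = 3)))
  expect_equal(build_bank_connectivity(b1),
               embed_imaginary(matrix(0, N, N), memory_item(i1$u, i1$v, rho = 3)),
               tolerance = 1e-14)

  # two orthonormal planes: spectrum {+-i, +-i, 0...}, rank 4, anti-symmetric
  q <- qr.Q(qr(matrix(stream_rnorm(st, "patterns", N * 4), N, 4)))
  items <- list(memory_item(q[, 1], q[, 2]), memory_item(q[, 3], q[, 4]))
  W <- build_bank_connectivity(memory_bank(items))
  ev <- eigen(W, only.values = TRUE)$values
  expect_equal(sort(Im(ev), decreasing = TRUE)[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(W, -t(W), tolerance = 1e-13)
  expect_equal(sum(Mod(ev) > 1e-8), 4L)
  expect_error(memory_bank(rep(items, 13)))  # M > N/2
})

test_that("the OU stimulus lives on the plane with the stated statistics", {
  st <- seed_streams(7)
  N <- 256
  it <- sample_memory(st, N)
  f <- ou_stimulus(it, t_on = 10, t_off = 60, dt = 0.1, streams = st,
                   amplitude = 1, sigma = 1)
  expect_equal(f(5), numeric(N))
  expect_equal(f(60), numeric(N))

  # in-span: projecting out the plane leaves nothing
  b <- f(30)
  B <- qr.Q(qr(cbind(it$u, it$v)))
  expect_equal(b - B %*% crossprod(B, b), matrix(0, N, 1), tolerance = 1e-12)

  # stationary coefficient variance ~ sigma^2, effectively white across steps
  cu <- attr(f, "c_u")
  expect_equal(stats::var(cu), 1, tolerance = 0.2)
  expect_lt(abs(stats::cor(cu[-1], cu[-length(cu)])), 0.15)  # lag-1 ~ e^{-10}
})

test_that("the retrieval cue is a finite pulse along u", {
  st <- seed_streams(7)
  it <- sample_memory(st, 32)
  f <- retrieval_cue(it, t_cue = 100)
  expect_equal(f(99.9), numeric(32))
  expect_equal(f(102.1), numeric(32))
  expect_equal(f(101), 10 * it$u)
  # v-projection of the cue is exactly zero in the item basis
  expect_equal(sum(f(100.5) * it$v) / sum(it$v^2) -
                 10 * sum(it$u * it$v) / sum(it$v^2), 0, tolerance = 1e-12)
})

test_that("input composition sums components", {
  st <- seed_streams(7)
  it <- sample_memory(st, 16)
  f1 <- retrieval_cue(it, 0, duration = 1, amplitude = 1)
  f2 <- retrieval_cue(it, 0.5, duration = 1, amplitude = 2)
  f <- compose_inputs(f1, f2, NULL)
  expect_equal(f(0.6), 3 * it$u)
  expect_null(compose_inputs(NULL))
})
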