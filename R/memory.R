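#' Connectivity matrix with optional sparsity mask
#'
#' Thin wrapper pairing an N x N weight matrix with an optional binary
#' structural mask. Wherever the mask is zero the weight is zero and every
#' plasticity update is zeroed too (absent synapses never appear). No
#' self-coupling constraint is imposed.
#'
#' @param W numeric N x N matrix (row i = postsynaptic neuron i).
#' @param mask optional binary N x N matrix.
#' @return object of class `connectivity`.
#' @export
connectivity <- function(W, mask = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (!is.null(mask)) {
    mask <- (as.matrix(mask) != 0) * 1
    if (!identical(dim(mask), dim(W))) stop("mask/W dimension mismatch", call. = FALSE)
    W <- W * mask
  }
  structure(list(W = W, mask = mask,
                 density = if (is.null(mask)) 1 else mean(mask)),
            class = "connectivity")
}

#' @export
as_weight_matrix <- function(W) UseMethod("as_weight_matrix")
#' @export
as_weight_matrix.connectivity <- function(W) W$W
#' @export
as_weight_matrix.matrix <- function(W) W
#' @export
as_weight_matrix.default <- function(W) as.matrix(W)

#' Random initial connectivity
#'
#' Draws \eqn{W_{ij} \sim N(0, g^2/N)} from the `init_W` stream (bulk
#' spectral radius approximately g for large N) and applies the structural
#' mask implied by `cfg$density` (drawn from the `patterns` stream when
#' `density < 1`).
#'
#' @param cfg a [sim_config()].
#' @param streams an [seed_streams()] object.
#' @return a [connectivity()] object.
#' @export
random_connectivity <- function(cfg, streams) {
  N <- cfg$N
  W <- matrix(stream_rnorm(streams, "init_W", N * N, sd = cfg$g / sqrt(N)), N, N)
  mask <- if (cfg$density < 1) {
    matrix(stream_runif(streams, "patterns", N * N) < cfg$density, N, N) * 1
  } else NULL
  connectivity(W, mask)
}

#' Memory item: a pattern pair spanning a plane
#'
#' A memory is a two-dimensional object: a pair of patterns (u, v) whose span
#' defines the memory plane, a strength `rho` (the magnitude of the imaginary
#' eigenvalue pair it induces), and a real-part coefficient `gamma` (the
#' symmetric rank-2 augmentation required, with gamma > 1, for a persistent
#' limit cycle in continuous time).
#'
#' @param u,v numeric pattern vectors of equal length.
#' @param rho memory strength (> 0).
#' @param gamma real-part coefficient (>= 0).
#' @return object of class `memory_item`.
#' @export
memory_item <- function(u, v, rho = 1, gamma = 0) {
  stopifnot(length(u) == length(v), rho > 0, gamma >= 0)
  structure(list(u = as.numeric(u), v = as.numeric(v), rho = rho, gamma = gamma),
            class = "memory_item")
}

#' Sample a random memory item
#'
#' Pattern entries are i.i.d. \eqn{N(0, 1/N)}, u and v mutually independent,
#' so for large N the patterns are approximately unit norm and orthogonal.
#'
#' @param streams an [seed_streams()] object (patterns stream is used).
#' @param N network size (>= 2).
#' @param rho,gamma see [memory_item()].
#' @param orthonormal orthonormalize the pair exactly (Gram-Schmidt)? Raw
#'   Gaussian patterns are the default; exact orthonormalization is useful
#'   for analytic spectrum checks.
#' @return a `memory_item`.
#' @export
sample_memory <- function(streams, N, rho = 1, gamma = 0, orthonormal = FALSE) {
  stopifnot(N >= 2)
  u <- stream_rnorm(streams, "patterns", N, sd = 1 / sqrt(N))
  v <- stream_rnorm(streams, "patterns", N, sd = 1 / sqrt(N))
  it <- memory_item(u, v, rho = rho, gamma = gamma)
  if (orthonormal) orthonormalize_item(it) else it
}

#' Orthonormalize a memory item's pattern pair (Gram-Schmidt on u, then v)
#' @param item a `memory_item`.
#' @return a `memory_item` with exactly orthonormal patterns.
#' @export
orthonormalize_item <- function(item) {
  u <- item$u / sqrt(sum(item$u^2))
  v <- item$v - sum(u * item$v) * u
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) stop("degenerate pattern pair", call. = FALSE)
  memory_item(u, v / nv, rho = item$rho, gamma = item$gamma)
}

#' Embed a real-coded (fixed-point) memory
#'
#' Adds the symmetric rank-1 perturbation \eqn{\delta W = a\,uu^\top},
#' inducing a real outlier eigenvalue in the direction of u.
#'
#' @param W connectivity (matrix or [connectivity()]).
#' @param u pattern vector.
#' @param amplitude scale a of the perturbation (default 1).
#' @return matrix (or `connectivity`, matching the input class) with the
#'   perturbation added; under a mask the perturbation is masked too.
#' @export
embed_real <- function(W, u, amplitude = 1) {
  dW <- amplitude * tcrossprod(u)
  .add_perturbation(W, dW)
}

#' Embed an imaginary-coded (limit-cycle) memory
#'
#' Adds \eqn{\delta W = \rho(uv^\top - vu^\top) + \gamma(uu^\top + vv^\top)}:
#' an anti-symmetric rank-2 rotation generator on the memory plane producing
#' a conjugate eigenvalue pair \eqn{\gamma \pm i\rho} (for orthonormal
#' patterns), plus the optional symmetric gamma-augmentation.
#'
#' @param W connectivity (matrix or [connectivity()]).
#' @param item a [memory_item()] carrying u, v, rho, gamma.
#' @return perturbed connectivity, same class as the input.
#' @export
embed_imaginary <- function(W, item) {
  u <- item$u; v <- item$v
  dW <- item$rho * (tcrossprod(u, v) - tcrossprod(v, u))
  if (item$gamma != 0) dW <- dW + item$gamma * (tcrossprod(u) + tcrossprod(v))
  .add_perturbation(W, dW)
}

.add_perturbation <- function(W, dW) {
  if (inherits(W, "connectivity")) {
    if (!is.null(W$mask)) dW <- dW * W$mask
    connectivity(W$W + dW, W$mask)
  } else {
    as_weight_matrix(W) + dW
  }
}

#' Bank of memory items
#'
#' Collects M items into the factorized form W = U D U' with U the N x 2M
#' matrix of interleaved columns u(k), v(k) and D block-diagonal with blocks
#' ((0, rho_k), (-rho_k, 0)).
#'
#' @param items list of [memory_item()]s (M <= N/2).
#' @return object of class `memory_bank` with fields `items`, `U`, `D`.
#' @export
memory_bank <- function(items) {
  stopifnot(length(items) >= 1)
  N <- length(items[[1]]$u)
  M <- length(items)
  if (M > N / 2) stop("at most N/2 memory planes fit in an N-neuron network", call. = FALSE)
  U <- matrix(0, N, 2 * M)
  D <- matrix(0, 2 * M, 2 * M)
  for (k in seq_len(M)) {
    it <- items[[k]]
    if (length(it$u) != N) stop("pattern length mismatch in bank", call. = FALSE)
    U[, 2 * k - 1] <- it$u
    U[, 2 * k] <- it$v
    D[2 * k - 1, 2 * k] <- it$rho
    D[2 * k, 2 * k - 1] <- -it$rho
  }
  structure(list(items = items, U = U, D = D), class = "memory_bank")
}

#' Connectivity of a memory bank
#'
#' Builds \eqn{W = U D U^\top + \gamma \sum_k (u_k u_k^\top + v_k v_k^\top)}.
#' For exactly orthogonal patterns this equals the sum of per-item
#' [embed_imaginary()] perturbations on a zero matrix.
#'
#' @param bank a [memory_bank()].
#' @param gamma real-part coefficient applied to every plane.
#' @return N x N weight matrix.
#' @export
build_bank_connectivity <- function(bank, gamma = 0) {
  W <- bank$U %*% bank$D %*% t(bank$U)
  if (gamma != 0) W <- W + gamma * tcrossprod(bank$U)
  W
}

#' Planar Ornstein-Uhlenbeck stimulus
#'
#' Builds the learning input \eqn{b(t) = c_u(t)\,u + c_v(t)\,v} on
#' [t_on, t_off), with c_u, c_v independent OU processes of timescale
#' `ou_timescale` (default 0.01, far below the integration step, so the
#' coefficients are effectively white across steps). The processes use the
#' exact OU discretization
#' \eqn{c \leftarrow c\,e^{-dt/\tau} + \sigma\sqrt{1 - e^{-2dt/\tau}}\,z} and
#' are scaled by `amplitude`. The default amplitude 10 makes the
#' instantaneous coefficient RMS equal to the standard retrieval-pulse
#' coefficient (c_u = 10), so learning and recall probe the network at a
#' common drive scale.
#'
#' @param item memory item supplying the plane (u, v).
#' @param t_on,t_off stimulation window (t_off > t_on).
#' @param dt integration step at which the path is sampled.
#' @param streams an [seed_streams()] object (stimulus stream).
#' @param amplitude scale of c_u, c_v.
#' @param ou_timescale OU correlation time.
#' @param sigma stationary standard deviation of the unscaled processes.
#' @return function of time returning the input vector; zero outside the
#'   window. The realized coefficient paths are attached as attributes
#'   `c_u`, `c_v`, `times`.
#' @export
ou_stimulus <- function(item, t_on, t_off, dt, streams,
                        amplitude = 10, ou_timescale = 0.01, sigma = 1) {
  if (t_off <= t_on) stop("t_off must exceed t_on", call. = FALSE)
  nsteps <- as.integer(ceiling((t_off - t_on) / dt)) + 1L
  a <- exp(-dt / ou_timescale)
  sdev <- sigma * sqrt(1 - a^2)
  z <- matrix(stream_rnorm(streams, "stimulus", 2L * nsteps), nsteps, 2L)
  cu <- numeric(nsteps); cv <- numeric(nsteps)
  cu[1] <- sigma * z[1, 1]; cv[1] <- sigma * z[1, 2]
  for (k in 2:nsteps) {
    cu[k] <- cu[k - 1] * a + sdev * z[k, 1]
    cv[k] <- cv[k - 1] * a + sdev * z[k, 2]
  }
  cu <- amplitude * cu
  cv <- amplitude * cv
  u <- item$u; v <- item$v
  f <- function(t) {
    if (t < t_on || t >= t_off) return(numeric(length(u)))
    k <- min(nsteps, 1L + as.integer(floor((t - t_on) / dt + 1e-9)))
    cu[k] * u + cv[k] * v
  }
  attr(f, "c_u") <- cu
  attr(f, "c_v") <- cv
  attr(f, "times") <- t_on + (seq_len(nsteps) - 1L) * dt
  f
}

#' Retrieval cue: a brief pulse along u
#'
#' The associative recall cue is a pulse of duration 2 neural time constants
#' along the u direction of the target plane, \eqn{c_u = 10, c_v = 0}
#' (both configurable).
#'
#' @param item target memory item.
#' @param t_cue onset time.
#' @param duration pulse length (default 2).
#' @param amplitude c_u during the pulse (default 10).
#' @param v_amplitude c_v during the pulse (default 0).
#' @return function of time returning the input vector; zero outside the pulse.
#' @export
retrieval_cue <- function(item, t_cue, duration = 2, amplitude = 10, v_amplitude = 0) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  u <- item$u; v <- item$v
  function(t) {
    if (t >= t_cue && t < t_cue + duration) amplitude * u + v_amplitude * v
    else numeric(length(u))
  }
}

#' Sum several input functions
#' @param ... functions of time (or NULLs, ignored).
#' @return function of time returning the summed input.
#' @export
compose_inputs <- function(...) {
  fns <- Filter(Negate(is.null), list(...))
  if (length(fns) == 0L) return(NULL)
  if (length(fns) == 1L) return(fns[[1L]])
  function(t) Reduce(`+`, lapply(fns, function(f) f(t)))
}
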