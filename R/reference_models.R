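#' Reduced two-dimensional limit-cycle system
#'
#' For an infinitely steep nonlinearity the full dynamics with one
#' anti-symmetric memory are well approximated by the projected plane
#' coordinates: \eqn{\dot p_u = -p_u + \rho q_v},
#' \eqn{\dot p_v = -p_v - \rho q_u}, with
#' \eqn{q_v = \arctan(p_v/|p_u|)} and the symmetric completion
#' \eqn{q_u = \arctan(p_u/|p_v|)} (at a vanishing denominator the arctan is
#' taken at its signed limit \eqn{\pm\pi/2}; the origin maps to itself).
#' `reduced_step` advances one explicit Euler step.
#'
#' @param s a `reduced_state` (list with `p_u`, `p_v`, `rho`), e.g. from
#'   [reduced_state()].
#' @param dt Euler step (> 0); the reference discretization is dt = 0.1.
#' @return updated `reduced_state`.
#' @export
reduced_step <- function(s, dt = 0.1) {
  stopifnot(dt > 0)
  qv <- .signed_arctan(s$p_v, s$p_u)
  qu <- .signed_arctan(s$p_u, s$p_v)
  p_u <- s$p_u + dt * (-s$p_u + s$rho * qv)
  p_v <- s$p_v + dt * (-s$p_v - s$rho * qu)
  reduced_state(p_u, p_v, s$rho)
}

.signed_arctan <- function(a, b) {
  if (b != 0) return(atan(a / abs(b)))
  if (a == 0) 0 else sign(a) * pi / 2
}

#' @rdname reduced_step
#' @param p_u,p_v plane coordinates.
#' @param rho memory strength (> 0).
#' @export
reduced_state <- function(p_u, p_v, rho) {
  stopifnot(is.finite(p_u), is.finite(p_v), rho > 0)
  structure(list(p_u = p_u, p_v = p_v, rho = rho), class = "reduced_state")
}

#' Integrate the reduced system
#'
#' @param p0 numeric length-2 initial coordinates.
#' @param rho memory strength.
#' @param duration total time.
#' @param dt Euler step (default 0.1).
#' @return matrix with columns `p_u`, `p_v` (one row per step).
#' @export
run_reduced <- function(p0, rho, duration, dt = 0.1) {
  nsteps <- as.integer(round(duration / dt))
  out <- matrix(NA_real_, nsteps, 2, dimnames = list(NULL, c("p_u", "p_v")))
  s <- reduced_state(p0[1], p0[2], rho)
  for (k in seq_len(nsteps)) {
    s <- reduced_step(s, dt)
    out[k, ] <- c(s$p_u, s$p_v)
  }
  out
}

#' Mean orbit radius of a planar trajectory
#'
#' Average radial coordinate over the final portion of a trajectory, the
#' standard amplitude readout for limit cycles in this package.
#'
#' @param traj two-column matrix of plane coordinates (or a `trajectory`
#'   with a single projected item).
#' @param discard_frac fraction of initial samples discarded as transient.
#' @return mean radius (scalar).
#' @export
orbit_amplitude <- function(traj, discard_frac = 0.5) {
  if (inherits(traj, "trajectory")) traj <- traj$proj[[1]][, 1:2]
  n <- nrow(traj)
  keep <- seq.int(floor(n * discard_frac) + 1L, n)
  mean(sqrt(rowSums(traj[keep, , drop = FALSE]^2)))
}

#' Compare the reduced system with the full steep-nonlinearity network
#'
#' Integrates (a) the full rate network with
#' \eqn{W = \rho(uv^\top - vu^\top) + \gamma(uu^\top + vv^\top)} under a
#' steep (sign) nonlinearity and (b) the reduced two-dimensional system, and
#' reports the relative difference of limit-cycle amplitude in the
#' (p_u, p_v) plane. The reduced system is integrated at the reference step
#' dt = 0.1; the full model at a finer step (default 0.01) to resolve its
#' fast in-plane rotation. With `gamma = 0` and a small step the full
#' continuous-time model spirals into the origin (no orbit) and the result
#' is flagged `collapsed`; the persistent orbit requires gamma > 1, or
#' discrete-time dynamics (see [discrete_step()]).
#'
#' @param rho memory strength.
#' @param gamma real-part coefficient of the embedded memory (default 1.5).
#' @param N network size for the full model.
#' @param streams an [seed_streams()] object for pattern sampling.
#' @param phi nonlinearity of the full model (default sign).
#' @param dt_full,dt_reduced integration steps.
#' @param duration integration time for both models.
#' @param collapse_tol amplitude below which the full model is declared
#'   collapsed to the origin.
#' @return list with `amp_full`, `amp_reduced`, `rel_diff`
#'   (|full - reduced| / full) and `collapsed`.
#' @export
reduced_vs_full <- function(rho = 4, gamma = 1.5, N = 512, streams = seed_streams(1),
                            phi = nonlinearity("sign"),
                            dt_full = 0.01, dt_reduced = 0.1,
                            duration = 200, collapse_tol = 0.05) {
  item <- sample_memory(streams, N, rho = rho, gamma = gamma, orthonormal = TRUE)
  W <- embed_imaginary(matrix(0, N, N), item)
  cfg <- sim_config(N = N, dt = dt_full, phi = phi)
  x0 <- sqrt(N) * item$u * 0.5
  traj <- run_trajectory(x0, W, NULL, duration, cfg, record_every = 1L,
                         project_items = list(item))
  amp_full <- orbit_amplitude(traj$proj[[1]][, 1:2])
  final_r <- traj$proj[[1]][nrow(traj$proj[[1]]), "r"]
  collapsed <- is.na(amp_full) || final_r < collapse_tol
  red <- run_reduced(c(0.5, 0), rho, duration, dt = dt_reduced)
  amp_reduced <- orbit_amplitude(red)
  rel_diff <- if (collapsed) NA_real_ else abs(amp_full - amp_reduced) / amp_full
  list(amp_full = amp_full, amp_reduced = amp_reduced,
       rel_diff = rel_diff, collapsed = collapsed)
}

## ---------------------------------------------------------------------------
## Discrete-time dynamics and the Hopfield baseline
## ---------------------------------------------------------------------------

#' Discrete-time network
#'
#' Synchronous map \eqn{x' = \phi(Wx)}. With the sign nonlinearity and
#' gamma = 0 this is the stable version of the model used for capacity
#' calculations (the continuous-time gamma = 0 model decays to the origin).
#'
#' @param W weight matrix.
#' @param phi a [nonlinearity()] (default sign).
#' @return object of class `discrete_net`.
#' @export
discrete_net <- function(W, phi = nonlinearity("sign")) {
  structure(list(W = as_weight_matrix(W), phi = phi), class = "discrete_net")
}

#' @rdname discrete_net
#' @param net a `discrete_net`.
#' @param x state vector.
#' @return the next state \eqn{\phi(Wx)}.
#' @export
discrete_step <- function(net, x) {
  apply_phi(as.numeric(net$W %*% x), net$phi)
}

#' Run the discrete-time map
#'
#' @param net a [discrete_net()].
#' @param x0 initial state.
#' @param steps number of synchronous updates.
#' @param project_items optional list of memory items to project onto.
#' @return list with `X` (steps x N states) or `proj` (per-item steps x 3),
#'   and final `x`.
#' @export
run_discrete <- function(net, x0, steps, project_items = NULL) {
  x <- as.numeric(x0)
  keep_x <- is.null(project_items)
  X <- if (keep_x) matrix(NA_real_, steps, length(x)) else NULL
  proj <- if (!keep_x) {
    lapply(project_items, function(it) matrix(NA_real_, steps, 3,
                                              dimnames = list(NULL, c("p_u", "p_v", "r"))))
  } else NULL
  for (k in seq_len(steps)) {
    x <- discrete_step(net, x)
    if (keep_x) X[k, ] <- x
    else for (i in seq_along(project_items)) proj[[i]][k, ] <- project_onto_plane(x, project_items[[i]])
  }
  list(X = X, proj = proj, x = x)
}

#' Symmetric Hopfield baseline
#'
#' Classic associative net with binary patterns:
#' \eqn{W = \frac1N \sum_k \xi^{(k)} \xi^{(k)\top}} (zero diagonal) and
#' synchronous sign updates. Serves as the fixed-point counterpart of the
#' planar limit-cycle memories in capacity comparisons.
#'
#' @param N network size.
#' @param M number of stored patterns (>= 1).
#' @param streams an [seed_streams()] object (`trials` stream).
#' @return list with `net` (a [discrete_net()]) and `patterns` (N x M of
#'   plus/minus 1).
#' @export
hopfield_baseline <- function(N, M, streams) {
  stopifnot(M >= 1)
  xi <- matrix(sign(stream_runif(streams, "trials", N * M) - 0.5), N, M)
  xi[xi == 0] <- 1
  W <- tcrossprod(xi) / N
  diag(W) <- 0
  list(net = discrete_net(W, nonlinearity("sign")), patterns = xi)
}

#' Pattern overlap of a Hopfield state
#' @param x state vector of plus/minus 1.
#' @param xi pattern vector.
#' @return overlap m = |xi . x| / N.
#' @export
hopfield_overlap <- function(x, xi) abs(sum(xi * x)) / length(x)
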