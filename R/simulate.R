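#' Simulate the coupled neural / synaptic dynamics
#'
#' Integrates the full model — neural state
#' \eqn{\dot x = -x + W\phi(x) + b(t)} and weights
#' \eqn{\dot W = \eta(\Delta_L + \Delta_F)} — by explicit Euler with a common
#' step, where \eqn{\Delta_L} is the rate-based STDP operator (optional) and
#' \eqn{\Delta_F} combines a homeostatic rule with activity-independent
#' synaptic noise. Weight snapshots are stored on a coarse stride for
#' spectral analysis (the eigendecomposition cost dominates, so it is never
#' computed inside the loop).
#'
#' @param cfg a [sim_config()].
#' @param W0 initial connectivity (matrix or [connectivity()]); `NULL` draws
#'   a random one via [random_connectivity()].
#' @param duration total simulated time.
#' @param streams an [seed_streams()] object; `NULL` seeds from `cfg$seed`.
#' @param input_fn external input function of time, or `NULL`.
#' @param hcfg a [homeostasis_config()].
#' @param stdp an [stdp_config()] to enable learning, or `NULL` for
#'   \eqn{\Delta_L = 0}.
#' @param x0 initial state; `NULL` draws entries N(0, 1/N) from `init_x`
#'   (small random state, breaking symmetry without biasing any plane).
#' @param ps initial [plasticity_state()]; `NULL` builds a zeroed one.
#' @param project_items list of memory items whose plane projections are
#'   recorded every `record_every` time units.
#' @param record_every stride (time units) for projection records; 0 disables.
#' @param snap_every stride (time units) for weight snapshots; 0 disables.
#' @param weight_trace optional 2-column index matrix of synapses whose
#'   weights are traced at every record.
#' @param t0 initial time (records and snapshots are aligned to it).
#' @return object of class `network_run`: list with final `W`, `x`, `t`,
#'   `ps`, the records (`times`, `proj`, `weight_traces`), snapshots
#'   (`snap_times`, `W_snaps`), and `contrib`, the temporal averages of
#'   \eqn{\frac1{N^2}\sum_{ij}|\Delta_{ij}|} for the learning, homeostatic
#'   and noise terms (activity-dependent = learning + homeostatic).
#' @export
simulate_network <- function(cfg, W0 = NULL, duration,
                             streams = NULL,
                             input_fn = NULL,
                             hcfg = homeostasis_config("none"),
                             stdp = NULL,
                             x0 = NULL, ps = NULL,
                             project_items = NULL,
                             record_every = 1,
                             snap_every = 10,
                             weight_trace = NULL,
                             t0 = 0) {
  N <- cfg$N
  dt <- cfg$dt
  eta <- cfg$eta
  phi <- cfg$phi
  if (is.null(streams)) streams <- seed_streams(cfg$seed)
  if (is.null(W0)) W0 <- random_connectivity(cfg, streams)
  mask <- if (inherits(W0, "connectivity")) W0$mask else NULL
  W <- as_weight_matrix(W0)
  stopifnot(nrow(W) == N)
  if (is.null(x0)) x0 <- stream_rnorm(streams, "init_x", N, sd = 1 / sqrt(N))
  x <- as.numeric(x0)
  if (is.null(ps)) {
    ps <- if (is.null(stdp)) plasticity_state(N, tau_x = hcfg$tau_x)
          else plasticity_state(N, tau_P = stdp$tau_P, tau_D = stdp$tau_D, tau_x = hcfg$tau_x)
  }
  if (identical(hcfg$rule, "rate_control") && is.null(hcfg$phi0)) {
    hcfg$phi0 <- stream_runif(streams, "patterns", N, min = -1, max = 1)
  }
  plastic <- !is.null(stdp) || hcfg$rule != "none" || hcfg$noise_on

  nsteps <- as.integer(round(duration / dt))
  rec_stride <- if (record_every > 0) max(1L, as.integer(round(record_every / dt))) else 0L
  snap_stride <- if (snap_every > 0) max(1L, as.integer(round(snap_every / dt))) else 0L
  nrec <- if (rec_stride > 0L) nsteps %/% rec_stride else 0L
  nsnap <- if (snap_stride > 0L) nsteps %/% snap_stride + 1L else 0L

  times <- numeric(nrec)
  proj <- if (!is.null(project_items) && nrec > 0L) {
    lapply(project_items, function(it) matrix(NA_real_, nrec, 3,
                                              dimnames = list(NULL, c("p_u", "p_v", "r"))))
  } else NULL
  wtr <- if (!is.null(weight_trace) && nrec > 0L) {
    matrix(NA_real_, nrec, nrow(weight_trace))
  } else NULL
  snap_times <- numeric(nsnap)
  W_snaps <- if (nsnap > 0L) vector("list", nsnap) else NULL
  if (nsnap > 0L) { snap_times[1L] <- t0; W_snaps[[1L]] <- W }

  acc_learn <- 0; acc_homeo <- 0; acc_noise <- 0
  irec <- 0L; isnap <- 1L
  t <- t0
  zero <- matrix(0, N, N)

  for (k in seq_len(nsteps)) {
    phi_x <- apply_phi(x, phi)
    if (plastic) {
      dL <- if (!is.null(stdp)) stdp_term(phi_x, ps, stdp) else zero
      dF <- fluctuation_term(x, W, ps, hcfg, cfg, streams, mask)
      if (!is.null(stdp) && !is.null(mask)) dL <- dL * mask
      W <- W + (dt * eta) * (dL + dF$total)
      acc_learn <- acc_learn + mean(abs(dL))
      acc_homeo <- acc_homeo + mean(abs(dF$homeo))
      acc_noise <- acc_noise + mean(abs(dF$noise))
    }
    b <- if (is.null(input_fn)) 0 else input_fn(t)
    x_new <- x + dt * (-x + as.numeric(W %*% phi_x) + b)
    ps <- update_filters(ps, x, phi, dt)
    x <- x_new
    t <- t0 + k * dt
    if (!all(is.finite(x)) || !all(is.finite(W))) .blowup_error(t)

    if (rec_stride > 0L && k %% rec_stride == 0L) {
      irec <- irec + 1L
      times[irec] <- t
      if (!is.null(proj)) {
        for (i in seq_along(project_items)) {
          proj[[i]][irec, ] <- project_onto_plane(x, project_items[[i]])
        }
      }
      if (!is.null(wtr)) wtr[irec, ] <- W[weight_trace]
    }
    if (snap_stride > 0L && k %% snap_stride == 0L) {
      isnap <- isnap + 1L
      snap_times[isnap] <- t
      W_snaps[[isnap]] <- W
    }
  }

  contrib <- if (plastic && nsteps > 0L) {
    list(learning = acc_learn / nsteps,
         homeostatic = acc_homeo / nsteps,
         noise = acc_noise / nsteps,
         activity_dependent = (acc_learn + acc_homeo) / nsteps)
  } else NULL

  structure(list(W = W, x = x, t = t, ps = ps, mask = mask,
                 times = times[seq_len(irec)],
                 proj = if (!is.null(proj)) lapply(proj, function(m) m[seq_len(irec), , drop = FALSE]) else NULL,
                 weight_traces = if (!is.null(wtr)) wtr[seq_len(irec), , drop = FALSE] else NULL,
                 snap_times = snap_times[seq_len(isnap)],
                 W_snaps = if (!is.null(W_snaps)) W_snaps[seq_len(isnap)] else NULL,
                 contrib = contrib, hcfg = hcfg, cfg = cfg),
            class = "network_run")
}
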