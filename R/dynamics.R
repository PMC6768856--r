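#' Network state
#'
#' The instantaneous state of the rate network: the synaptic-input vector
#' \eqn{x} (pre-activation; rates are \eqn{\phi(x)}) and the simulation time
#' in units of the neural time constant.
#'
#' @param x numeric vector of length N, all entries finite.
#' @param t simulation time.
#' @return object of class `network_state`.
#' @export
network_state <- function(x, t = 0) {
  if (!all(is.finite(x))) stop("network state must be finite", call. = FALSE)
  structure(list(x = as.numeric(x), t = t), class = "network_state")
}

.blowup_error <- function(t) {
  stop(errorCondition(
    sprintf("integration blew up (non-finite state) at t = %.4f", t),
    t = t, class = c("dynmem_blowup", "error")
  ))
}

#' One Euler step of the neural dynamics
#'
#' Advances \eqn{\dot x = -x + W\phi(x) + b(t)} by one explicit Euler step:
#' \eqn{x \leftarrow x + dt\,(-x + W\phi(x) + b)}, \eqn{t \leftarrow t + dt}.
#'
#' @param state a [network_state()].
#' @param W N x N connectivity matrix (or a `connectivity` object).
#' @param b external-input vector (length N), or a single 0.
#' @param cfg a [sim_config()].
#' @return the updated `network_state`.
#' @export
step_activity <- function(state, W, b, cfg) {
  W <- as_weight_matrix(W)
  x <- state$x
  if (length(x) != nrow(W)) stop("state/connectivity dimension mismatch", call. = FALSE)
  xn <- x + cfg$dt * (-x + as.numeric(W %*% apply_phi(x, cfg$phi)) + b)
  if (!all(is.finite(xn))) .blowup_error(state$t + cfg$dt)
  network_state(xn, state$t + cfg$dt)
}

#' Integrate a trajectory under fixed connectivity
#'
#' Runs the neural dynamics for a given duration with connectivity held
#' fixed, recording the state every `record_every` steps. Deterministic given
#' the initial state and input function.
#'
#' @param x0 initial state vector (length N).
#' @param W fixed N x N connectivity.
#' @param input_fn function of time returning the input vector b(t), or
#'   `NULL` for no input.
#' @param duration total integration time (> 0).
#' @param cfg a [sim_config()].
#' @param record_every record stride in steps (default 1).
#' @param t0 initial time.
#' @param project_items optional list of memory items; when given, per-item
#'   plane projections (p_u, p_v, r) are recorded instead of the full state,
#'   which is cheaper for large N.
#' @return object of class `trajectory`: list with `times`, `X` (recorded
#'   states, one row per record, or `NULL` when projecting), `proj` (list of
#'   T x 3 matrices per item), and the final `state`.
#' @export
run_trajectory <- function(x0, W, input_fn = NULL, duration, cfg,
                           record_every = 1L, t0 = 0, project_items = NULL) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  W <- as_weight_matrix(W)
  nsteps <- as.integer(round(duration / cfg$dt))
  record_every <- max(1L, as.integer(record_every))
  nrec <- nsteps %/% record_every
  keep_x <- is.null(project_items)
  X <- if (keep_x) matrix(NA_real_, nrec, length(x0)) else NULL
  proj <- if (!keep_x) {
    lapply(project_items, function(it) matrix(NA_real_, nrec, 3,
                                              dimnames = list(NULL, c("p_u", "p_v", "r"))))
  } else NULL
  times <- numeric(nrec)
  x <- as.numeric(x0)
  t <- t0
  dt <- cfg$dt
  phi <- cfg$phi
  irec <- 0L
  for (k in seq_len(nsteps)) {
    b <- if (is.null(input_fn)) 0 else input_fn(t)
    x <- x + dt * (-x + as.numeric(W %*% apply_phi(x, phi)) + b)
    t <- t0 + k * dt
    if (!all(is.finite(x))) .blowup_error(t)
    if (k %% record_every == 0L) {
      irec <- irec + 1L
      times[irec] <- t
      if (keep_x) {
        X[irec, ] <- x
      } else {
        for (i in seq_along(project_items)) {
          proj[[i]][irec, ] <- project_onto_plane(x, project_items[[i]])
        }
      }
    }
  }
  structure(list(times = times, X = X, proj = proj,
                 state = network_state(x, t)),
            class = "trajectory")
}

#' Write a trajectory as a CSV time series
#'
#' Columns are `time, x_0, ..., x_{N-1}` (or the recorded plane projections
#' when the trajectory was projected).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!is.null(traj$X)) {
    df <- data.frame(time = traj$times, traj$X)
    names(df) <- c("time", paste0("x_", seq_len(ncol(traj$X)) - 1L))
  } else {
    df <- data.frame(time = traj$times)
    for (i in seq_along(traj$proj)) {
      block <- as.data.frame(traj$proj[[i]])
      names(block) <- paste0(c("p_u_", "p_v_", "r_"), i)
      df <- cbind(df, block)
    }
  }
  utils::write.csv(.format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE)
}
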