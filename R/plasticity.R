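#' Low-pass filter state used by plasticity rules
#'
#' First-order low-passed traces of activity: `yP` and `yD` filter the rates
#' \eqn{\phi(x)} with the STDP kernel timescales (tau_P, tau_D; a single
#' tau = 50 in the anti-symmetric case), and `xbar` filters the state x with
#' timescale tau_x = 20 for the decorrelation rule.
#'
#' @param N network size.
#' @param tau_P,tau_D,tau_x filter timescales (> 0).
#' @return object of class `plasticity_state`.
#' @export
plasticity_state <- function(N, tau_P = 50, tau_D = 50, tau_x = 20) {
  stopifnot(tau_P > 0, tau_D > 0, tau_x > 0)
  structure(list(yP = numeric(N), yD = numeric(N), xbar = numeric(N),
                 tau_P = tau_P, tau_D = tau_D, tau_x = tau_x),
            class = "plasticity_state")
}

#' Advance the low-pass filters by one Euler step
#'
#' \eqn{y \leftarrow y + dt\,(\phi(x) - y)/\tau} for yP and yD, and
#' analogously for xbar with the raw state x.
#'
#' @param ps a [plasticity_state()].
#' @param x current state vector.
#' @param phi a [nonlinearity()].
#' @param dt integration step.
#' @return updated `plasticity_state`.
#' @export
update_filters <- function(ps, x, phi, dt) {
  phi_x <- apply_phi(x, phi)
  ps$yP <- ps$yP + dt * (phi_x - ps$yP) / ps$tau_P
  ps$yD <- if (ps$tau_D == ps$tau_P) ps$yP else ps$yD + dt * (phi_x - ps$yD) / ps$tau_D
  ps$xbar <- ps$xbar + dt * (x - ps$xbar) / ps$tau_x
  ps
}

#' Activity-independent synaptic noise
#'
#' A fresh i.i.d. draw \eqn{\xi_{ij} \sim N(0, 1/N)} for every synapse,
#' independent across time and synapses; zeroed under the structural mask.
#'
#' @param streams an [seed_streams()] object (the `noise` stream is consumed).
#' @param N network size.
#' @param mask optional binary mask.
#' @return N x N noise matrix.
#' @export
noise_term <- function(streams, N, mask = NULL) {
  xi <- matrix(stream_rnorm(streams, "noise", N * N, sd = 1 / sqrt(N)), N, N)
  if (!is.null(mask)) xi <- xi * mask
  xi
}

#' Dissipation homeostasis term
#'
#' Returns \eqn{-\beta W}; the noise is added separately by the combiner.
#' With learning and noise off this yields \eqn{W(t) = W(0)\,e^{-\eta\beta t}}
#' so every eigenvalue (real- or imaginary-coded alike) decays at rate
#' \eqn{\eta\beta}.
#'
#' @param W weight matrix.
#' @param beta dissipation rate (> 0).
#' @return N x N matrix.
#' @export
dissipation_term <- function(W, beta) {
  stopifnot(beta > 0)
  -beta * as_weight_matrix(W)
}

#' Rate-control homeostasis term
#'
#' \eqn{[(\phi_0 - \phi(x))\,\phi(x)^\top] \circ W}: each synapse ij is
#' scaled by a factor depending on its post-synaptic rate error
#' \eqn{\phi_{0,i} - \phi(x_i)} and its pre-synaptic rate \eqn{\phi(x_j)},
#' stabilizing post-synaptic firing around the set-point phi0.
#'
#' @param x state vector.
#' @param W weight matrix.
#' @param phi0 target-rate vector.
#' @param phi a [nonlinearity()].
#' @return N x N matrix, entry (i,j) = (phi0_i - phi(x_i)) * phi(x_j) * W_ij.
#' @export
rate_control_term <- function(x, W, phi0, phi = nonlinearity("tanh")) {
  W <- as_weight_matrix(W)
  phi_x <- apply_phi(x, phi)
  outer(phi0 - phi_x, phi_x) * W
}

#' Decorrelation homeostasis term
#'
#' \eqn{I - \phi_{post}(x)\,\phi_{pre}(x)^\top} with
#' \eqn{\phi_{pre}(x) = \phi(x)} and \eqn{\phi_{post}(x) = \phi(x - \bar x)}:
#' an anti-Hebbian term weakening connections between correlated neurons
#' (no firing-rate set-point), plus an identity leak that keeps the network
#' from silencing itself.
#'
#' @param x state vector.
#' @param xbar low-passed state (timescale tau_x).
#' @param phi a [nonlinearity()] (tanh in the reference model).
#' @return N x N matrix.
#' @export
decorrelation_term <- function(x, xbar, phi = nonlinearity("tanh")) {
  post <- apply_phi(x - xbar, phi)
  pre <- apply_phi(x, phi)
  diag(length(x)) - outer(post, pre)
}

#' Rate-based STDP learning term
#'
#' The learning operator obtained by averaging an exponential STDP kernel
#' over Poisson spiking at slowly varying rates:
#' \eqn{[\Delta_L]_{ij} = a_P\,\phi_i\,y^P_j + a_D\,\phi_j\,y^D_i}
#' — potentiation for pre-before-post ordering (filtered pre rate times
#' current post rate) and depression (\eqn{a_D < 0}) for the reverse order.
#' The plasticity rate eta is applied once, by the combiner, never here.
#' For the anti-symmetric kernel (tau_P = tau_D, a_D = -a_P) this reduces to
#' \eqn{a_P(\phi y^\top - y\phi^\top)}, which modifies only the
#' anti-symmetric component of W.
#'
#' @param phi_x rate vector \eqn{\phi(x)}.
#' @param ps a [plasticity_state()] carrying the filtered rates.
#' @param stdp an [stdp_config()].
#' @return N x N matrix.
#' @export
stdp_term <- function(phi_x, ps, stdp) {
  stdp$a_P * tcrossprod(phi_x, ps$yP) + stdp$a_D * tcrossprod(ps$yD, phi_x)
}

#' Advance the weights by one Euler step
#'
#' \eqn{W \leftarrow W + dt\,\eta\,(\Delta_L + \Delta_F)}; masked entries
#' remain exactly zero.
#'
#' @param W weight matrix.
#' @param delta_L learning term (matrix or 0).
#' @param delta_F fluctuation term (matrix or 0).
#' @param eta plasticity rate.
#' @param dt integration step.
#' @param mask optional binary mask.
#' @return updated weight matrix.
#' @export
step_weights <- function(W, delta_L, delta_F, eta, dt, mask = NULL) {
  W <- as_weight_matrix(W)
  dW <- delta_L + delta_F
  if (!is.null(mask)) dW <- dW * mask
  Wn <- W + dt * eta * dW
  if (!all(is.finite(Wn))) .blowup_error(NA_real_)
  Wn
}

#' Fluctuation term for one step
#'
#' Assembles \eqn{\Delta_F} = homeostatic rule term + synaptic noise,
#' consuming the noise stream once per call when noise is on. Under the
#' `sqrt_dt` convention the noise draw is rescaled by \eqn{1/\sqrt{dt}} so
#' that the accumulated weight variance is independent of the step size.
#'
#' @param x state vector.
#' @param W weight matrix.
#' @param ps a [plasticity_state()].
#' @param hcfg a [homeostasis_config()].
#' @param cfg a [sim_config()].
#' @param streams an [seed_streams()] object.
#' @param mask optional binary mask.
#' @return list with components `total` (the matrix \eqn{\Delta_F}),
#'   `homeo` (rule part) and `noise` (noise part), for contribution
#'   accounting.
#' @export
fluctuation_term <- function(x, W, ps, hcfg, cfg, streams, mask = NULL) {
  N <- cfg$N
  homeo <- switch(hcfg$rule,
    none = matrix(0, N, N),
    dissipation = dissipation_term(W, hcfg$beta),
    rate_control = rate_control_term(x, W, hcfg$phi0, cfg$phi),
    decorrelation = decorrelation_term(x, ps$xbar, cfg$phi)
  )
  if (hcfg$noise_on) {
    xi <- noise_term(streams, N, mask)
    if (hcfg$noise_convention == "sqrt_dt") xi <- xi / sqrt(cfg$dt)
  } else {
    xi <- matrix(0, N, N)
  }
  if (!is.null(mask)) homeo <- homeo * mask
  list(total = homeo + xi, homeo = homeo, noise = xi)
}
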