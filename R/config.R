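#' Simulation configuration
#'
#' Bundles the network-level constants of the model: size, integration step,
#' plasticity rate, the nonlinearity, and the scale of the random initial
#' connectivity. Defaults follow the reference parameterization of the model
#' (N = 128 neurons, Euler step dt = 0.1 in units of the neural time constant,
#' plasticity rate eta = 0.01, tanh rates, initial weights
#' \eqn{W_{ij} \sim N(0, g^2/N)} with g = 1).
#'
#' @param N number of neurons (positive integer).
#' @param dt Euler integration step, in units of the neural time constant.
#' @param eta plasticity rate relative to the neural dynamics.
#' @param seed master integer seed; all randomness derives from it via
#'   [seed_streams()].
#' @param phi a [nonlinearity()] (or its kind as a string).
#' @param g standard-deviation scale of the initial random connectivity
#'   (bulk spectral radius for large N).
#' @param density structural connection density in (0, 1]; densities below 1
#'   impose a fixed binary sparsity mask on W and on every plasticity update.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(N = 128L, dt = 0.1, eta = 0.01, seed = 1L,
                       phi = nonlinearity("tanh"), g = 1, density = 1) {
  if (is.character(phi)) phi <- nonlinearity(phi)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == round(N))
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!is.numeric(eta) || eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  if (!is.numeric(density) || density <= 0 || density > 1) {
    stop("`density` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(N = as.integer(N), dt = dt, eta = eta, seed = as.integer(seed),
         phi = phi, g = g, density = density),
    class = "sim_config"
  )
}

#' STDP kernel parameters
#'
#' Parameters of the exponential spike-timing kernel underlying the rate-based
#' learning rule: potentiation amplitude/timescale (`a_P`, `tau_P`) for
#' pre-before-post lags and depression amplitude/timescale (`a_D`, `tau_D`)
#' for post-before-pre. The kernel is purely anti-symmetric iff
#' `tau_P == tau_D` and `a_D == -a_P`, in which case the learning operator
#' reduces to \eqn{a_P(\phi y^\top - y \phi^\top)} and only modifies the
#' anti-symmetric component of W.
#'
#' @param a_P potentiation amplitude (> 0).
#' @param a_D depression amplitude (< 0).
#' @param tau_P,tau_D filter timescales of the low-passed rates (default 50).
#' @return object of class `stdp_config`.
#' @export
stdp_config <- function(a_P = 1, a_D = -1, tau_P = 50, tau_D = 50) {
  if (a_P <= 0) stop("`a_P` must be positive", call. = FALSE)
  if (a_D >= 0) stop("`a_D` must be negative", call. = FALSE)
  if (tau_P <= 0 || tau_D <= 0) stop("kernel timescales must be positive", call. = FALSE)
  structure(list(a_P = a_P, a_D = a_D, tau_P = tau_P, tau_D = tau_D),
            class = "stdp_config")
}

#' Is an STDP configuration purely anti-symmetric?
#' @param stdp an [stdp_config()].
#' @return logical.
#' @export
is_antisymmetric_stdp <- function(stdp) {
  isTRUE(all.equal(stdp$tau_P, stdp$tau_D)) && isTRUE(all.equal(stdp$a_D, -stdp$a_P))
}

#' Homeostasis / fluctuation configuration
#'
#' Selects the homeostatic component of the fluctuation term and the synaptic
#' noise. Exactly one rule is active:
#' \describe{
#'   \item{dissipation}{\eqn{-\beta W}: uniform exponential decay of all
#'     weights (rate `beta`, default 0.1).}
#'   \item{rate_control}{\eqn{[(\phi_0 - \phi(x))\,\phi(x)^\top] \circ W}:
#'     multiplicative scaling of each synapse towards a post-synaptic
#'     target-rate vector `phi0` (entries drawn uniformly on [-1, 1] when not
#'     supplied).}
#'   \item{decorrelation}{\eqn{I - \phi_{post}(x)\,\phi_{pre}(x)^\top} with
#'     \eqn{\phi_{pre}(x) = \tanh(x)} and
#'     \eqn{\phi_{post}(x) = \tanh(x - \bar x)}, \eqn{\bar x} a low-passed
#'     state (timescale `tau_x` = 20): an anti-Hebbian push towards
#'     decorrelated rates, with no explicit rate set-point.}
#'   \item{none}{no homeostasis (noise only, if enabled).}
#' }
#' Synaptic noise is i.i.d. \eqn{\xi_{ij} \sim N(0, 1/N)}, fresh each weight
#' update. Under the default `per_step` convention the draw enters the
#' fluctuation term directly (scaled by `dt * eta` like every other term);
#' `sqrt_dt` rescales it by \eqn{1/\sqrt{dt}} so that the accumulated variance
#' is step-size invariant (diffusion convention).
#'
#' @param rule one of `"dissipation"`, `"rate_control"`, `"decorrelation"`, `"none"`.
#' @param beta dissipation rate (> 0).
#' @param phi0 target-rate vector for rate control, or `NULL` to draw it
#'   uniformly on [-1, 1] from the pattern stream at simulation setup.
#' @param noise_on logical; include the synaptic white-noise term?
#' @param noise_convention `"per_step"` (default) or `"sqrt_dt"`.
#' @param tau_x timescale of the low-passed state used by decorrelation.
#' @return object of class `homeo_config`.
#' @export
homeostasis_config <- function(rule = c("none", "dissipation", "rate_control", "decorrelation"),
                               beta = 0.1, phi0 = NULL, noise_on = TRUE,
                               noise_convention = c("per_step", "sqrt_dt"),
                               tau_x = 20) {
  rule <- match.arg(rule)
  noise_convention <- match.arg(noise_convention)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  structure(
    list(rule = rule, beta = beta, phi0 = phi0, noise_on = isTRUE(noise_on),
         noise_convention = noise_convention, tau_x = tau_x),
    class = "homeo_config"
  )
}

## ---------------------------------------------------------------------------
## Named independent random streams
## ---------------------------------------------------------------------------

.stream_names <- c("init_W", "init_x", "noise", "patterns", "stimulus", "trials")

.substream_seed <- function(master, k) {
  # deterministic integer mix, exact in double arithmetic (< 2^53)
  as.integer((abs(as.double(master)) %% 2147483647 * 48271 + 104729 * k) %% 2147483629)
}

#' Named independent random streams
#'
#' Derives a set of named, independently seeded random streams from one master
#' seed: `init_W` (initial connectivity), `init_x` (initial state), `noise`
#' (synaptic white noise), `patterns` (memory patterns, masks, target rates),
#' `stimulus` (external drive), and `trials` (per-trial randomness in capacity
#' runs). Drawing from one stream never advances another, so paired
#' experiments can, e.g., change the stimulus while reusing an identical
#' noise realization.
#'
#' @param master_seed integer master seed.
#' @return object of class `rng_streams`.
#' @examples
#' s <- seed_streams(42)
#' a <- stream_rnorm(s, "noise", 3)
#' b <- stream_rnorm(s, "patterns", 3)  # independent of the noise stream
#' @export
seed_streams <- function(master_seed) {
  env <- new.env(parent = emptyenv())
  keep <- .save_rng()
  on.exit(.restore_rng(keep), add = TRUE)
  for (k in seq_along(.stream_names)) {
    set.seed(.substream_seed(master_seed, k), kind = "Mersenne-Twister")
    env[[.stream_names[k]]] <- get(".Random.seed", envir = globalenv())
  }
  structure(list(env = env, master_seed = as.integer(master_seed)),
            class = "rng_streams")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(keep) {
  if (is.null(keep)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", keep, envir = globalenv())
  }
}

#' Draw from a named stream
#'
#' `stream_eval()` evaluates an arbitrary random expression under the state of
#' one stream; `stream_rnorm()`/`stream_runif()` are the common cases.
#'
#' @param streams an [seed_streams()] object.
#' @param name stream name.
#' @param fn zero-argument function performing the draws.
#' @return the value of `fn()`.
#' @export
stream_eval <- function(streams, name, fn) {
  stopifnot(inherits(streams, "rng_streams"))
  if (is.null(streams$env[[name]])) stop("unknown stream: ", name, call. = FALSE)
  keep <- .save_rng()
  assign(".Random.seed", streams$env[[name]], envir = globalenv())
  out <- fn()
  streams$env[[name]] <- get(".Random.seed", envir = globalenv())
  .restore_rng(keep)
  out
}

#' @rdname stream_eval
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @export
stream_rnorm <- function(streams, name, n, mean = 0, sd = 1) {
  stream_eval(streams, name, function() stats::rnorm(n, mean, sd))
}

#' @rdname stream_eval
#' @param min,max uniform bounds.
#' @export
stream_runif <- function(streams, name, n, min = 0, max = 1) {
  stream_eval(streams, name, function() stats::runif(n, min, max))
}

#' Clone the state of a set of streams
#'
#' Returns an independent copy whose subsequent draws do not affect the
#' original. Used by paired experiments: after a shared burn-in, each branch
#' receives a clone, so both consume an identical noise realization.
#'
#' @param streams an [seed_streams()] object.
#' @return a new `rng_streams` object with identical current state.
#' @export
clone_streams <- function(streams) {
  env <- new.env(parent = emptyenv())
  for (nm in ls(streams$env)) env[[nm]] <- streams$env[[nm]]
  structure(list(env = env, master_seed = streams$master_seed),
            class = "rng_streams")
}

## ---------------------------------------------------------------------------
## Structured-text run configuration
## ---------------------------------------------------------------------------

.config_defaults <- function() {
  list(
    network = list(N = 128L, dt = 0.1, eta = 0.01, seed = 1L, g = 1,
                   density = 1,
                   phi = list(kind = "tanh", gain = 1, floor = -5)),
    plasticity = list(rule = "none", beta = 0.1, noise_on = TRUE,
                      noise_convention = "per_step", tau_x = 20,
                      stdp = list(a_P = 1, a_D = -1, tau_P = 50, tau_D = 50)),
    protocol = list(),
    output = list(dir = ".", snap_every = 10, record_every = 1)
  )
}

# YAML 1.1 coerces a bare key `N` to a boolean; restore it
.fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "N", nm)
  lapply(x, .fix_yaml_keys)
}

.merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", paste(here, collapse = "."), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !identical(key, "protocol")) {
      if (!is.list(user[[key]])) {
        stop("configuration key ", paste(here, collapse = "."),
             " must be a mapping", call. = FALSE)
      }
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  n <- cfg$network
  if (!is.numeric(n$N) || n$N < 2 || n$N != round(n$N)) {
    stop("invalid configuration value at network.N", call. = FALSE)
  }
  if (!is.numeric(n$dt) || n$dt <= 0) stop("invalid configuration value at network.dt", call. = FALSE)
  if (!is.numeric(n$eta) || n$eta <= 0) stop("invalid configuration value at network.eta", call. = FALSE)
  if (!n$phi$kind %in% c("tanh", "rectified_linear", "sign", "tanh_gain")) {
    stop("invalid configuration value at network.phi.kind", call. = FALSE)
  }
  if (!cfg$plasticity$rule %in% c("none", "dissipation", "rate_control", "decorrelation")) {
    stop("invalid configuration value at plasticity.rule", call. = FALSE)
  }
  if (!cfg$plasticity$noise_convention %in% c("per_step", "sqrt_dt")) {
    stop("invalid configuration value at plasticity.noise_convention", call. = FALSE)
  }
  if (!is.numeric(cfg$network$density) || cfg$network$density <= 0 || cfg$network$density > 1) {
    stop("invalid configuration value at network.density", call. = FALSE)
  }
  for (ev in cfg$protocol) {
    if (!is.list(ev) || is.null(ev$type) || !ev$type %in% c("stimulus", "cue")) {
      stop("protocol events must be mappings with type 'stimulus' or 'cue'", call. = FALSE)
    }
  }
  cfg
}

#' Load / save a run configuration
#'
#' Reads a YAML run configuration, fills unspecified keys with the reference
#' defaults (N = 128, dt = 0.1, eta = 0.01, tau = 50, tau_x = 20, beta = 0.1,
#' tanh rates), rejects unknown keys, and validates values. An empty file
#' yields the all-defaults configuration.
#'
#' @param path path to a YAML file.
#' @return a validated `run_config` list with components `network`,
#'   `plasticity`, `protocol` and `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  user <- .fix_yaml_keys(user)
  cfg <- .validate_config(.merge_config(.config_defaults(), user))
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config` (or plain list with the same shape).
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a [sim_config()] and [homeostasis_config()] from a run configuration
#' @param cfg a `run_config` from [load_config()].
#' @return list with components `sim`, `homeo`, `stdp`.
#' @export
config_objects <- function(cfg) {
  n <- cfg$network
  phi <- nonlinearity(n$phi$kind, gain = n$phi$gain, floor = n$phi$floor)
  list(
    sim = sim_config(N = n$N, dt = n$dt, eta = n$eta, seed = n$seed,
                     phi = phi, g = n$g, density = n$density),
    homeo = homeostasis_config(cfg$plasticity$rule, beta = cfg$plasticity$beta,
                               noise_on = cfg$plasticity$noise_on,
                               noise_convention = cfg$plasticity$noise_convention,
                               tau_x = cfg$plasticity$tau_x),
    stdp = do.call(stdp_config, cfg$plasticity$stdp)
  )
}
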