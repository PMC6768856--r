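#' Half-life of a decaying amplitude trace
#'
#' Time after onset at which the baseline-subtracted amplitude first falls
#' below half its initial (post-embedding) value, with linear interpolation
#' between snapshots. Returns `Inf` when the amplitude never crosses the
#' threshold within the horizon ("not decayed").
#'
#' @param times snapshot times (relative to embedding).
#' @param amp amplitude readout at each snapshot.
#' @param baseline bulk-edge baseline subtracted from the amplitude.
#' @param a0 initial amplitude; defaults to the first sample.
#' @return half-life in time units, possibly `Inf`.
#' @export
half_life <- function(times, amp, baseline = 0, a0 = amp[1]) {
  thr <- baseline + (a0 - baseline) / 2
  below <- which(amp <= thr)
  below <- below[below > 1L]
  if (length(below) == 0L) return(Inf)
  j <- below[1L]
  t1 <- times[j - 1L]; t2 <- times[j]
  a1 <- amp[j - 1L]; a2 <- amp[j]
  if (a1 == a2) return(t2)
  t1 + (a1 - thr) / (a1 - a2) * (t2 - t1)
}

.amplitude_trace <- function(snaps, kind, item) {
  vapply(snaps, function(W) {
    if (kind == "real") {
      Re(aligned_real_eigenvalue(W, item$u)$lambda)
    } else {
      mp <- memory_eigenpair(W, item)
      if (mp$absent) 0 else abs(Im(mp$lambda))
    }
  }, numeric(1))
}

#' Memory-erosion experiment
#'
#' Paired comparison of real-coded vs imaginary-coded memory decay under a
#' homeostatic rule with activity-independent synaptic noise and no active
#' learning. After a shared burn-in, a memory is embedded either as a
#' symmetric rank-1 perturbation \eqn{a\,uu^\top} (real outlier) or an
#' anti-symmetric rank-2 perturbation \eqn{a(uv^\top - vu^\top)} (imaginary
#' pair), with `a` scaled to `embed_scale` times the bulk spectral radius at
#' embedding time. Both sub-runs consume an identical noise realization
#' (cloned streams), and the memory eigenvalue amplitude (real part of the
#' aligned outlier, |Im| of the matched pair) is tracked at snapshot times
#' to fit half-lives.
#'
#' @param rule homeostatic rule: `"dissipation"`, `"rate_control"` or
#'   `"decorrelation"`.
#' @param N network size (default 64 for routine runs).
#' @param seed master seed.
#' @param horizon tracking window after embedding (time units).
#' @param burn_in settling time before embedding.
#' @param embed_scale outlier amplitude in units of the bulk radius. The
#'   default places the outlier just outside the instability boundary: a
#'   barely supercritical real outlier ignites weak activity that homeostasis
#'   can act on, whereas a deeply saturated frozen state lets the
#'   multiplicative rate-control rule amplify itself.
#' @param noise_on include synaptic noise? (The dissipation closed form is
#'   exposed with noise off.)
#' @param snap_every snapshot stride (time units).
#' @param density structural connection density.
#' @param dt,eta,g,beta model constants (see [sim_config()] and
#'   [homeostasis_config()]).
#' @param phi the rate nonlinearity (tanh by default; the rectified-linear
#'   unit with its negative floor is the variant under which rate-control
#'   homeostasis acts most cleanly, since rates are not saturated).
#' @return object of class `erosion_report`: rule, half-lives, their ratio
#'   (imaginary/real, horizon-censored values entered at the horizon),
#'   amplitude traces, the embedding amplitude and bulk baselines, and
#'   decay-rate fits.
#' @export
erosion_experiment <- function(rule, N = 64, seed = 1, horizon = 5000,
                               burn_in = 200, embed_scale = 1.5, noise_on = TRUE,
                               snap_every = 10, density = 1,
                               dt = 0.1, eta = 0.01, g = 0.8, beta = 0.1,
                               phi = nonlinearity("tanh")) {
  rule <- match.arg(rule, c("dissipation", "rate_control", "decorrelation"))
  cfg <- sim_config(N = N, dt = dt, eta = eta, seed = seed, g = g, density = density,
                    phi = phi)
  streams <- seed_streams(seed)
  hcfg <- homeostasis_config(rule, beta = beta, noise_on = noise_on)
  W0 <- random_connectivity(cfg, streams)
  mask <- W0$mask
  item <- orthonormalize_item(sample_memory(streams, N))

  burn <- simulate_network(cfg, W0, duration = burn_in, streams = streams,
                           hcfg = hcfg, record_every = 0, snap_every = 0)
  hcfg <- burn$hcfg  # realized phi0, if any
  ev_pre <- eigen(burn$W, only.values = TRUE)$values
  bulk_radius <- max(Mod(ev_pre))
  baseline_real <- max(Re(ev_pre))
  baseline_imag <- max(Im(ev_pre))
  a_embed <- embed_scale * bulk_radius

  # integrate each branch in chunks so that an integration blowup (possible
  # under a destabilized homeostatic regime) yields a truncated report with
  # diagnostics rather than an error
  run_branch <- function(kind) {
    dW <- if (kind == "real") {
      a_embed * tcrossprod(item$u)
    } else {
      a_embed * (tcrossprod(item$u, item$v) - tcrossprod(item$v, item$u))
    }
    if (!is.null(mask)) dW <- dW * mask
    W <- burn$W + dW
    br_streams <- clone_streams(streams)
    x <- burn$x; psb <- burn$ps; t <- burn$t
    chunk <- max(snap_every * 10, 100)
    snaps <- list(W); stimes <- t
    blew <- FALSE
    remaining <- horizon
    while (remaining > 1e-9) {
      dur <- min(chunk, remaining)
      run <- tryCatch(
        simulate_network(cfg, connectivity(W, mask), duration = dur,
                         streams = br_streams, hcfg = hcfg, x0 = x, ps = psb,
                         t0 = t, record_every = 0, snap_every = snap_every),
        dynmem_blowup = function(e) e
      )
      if (inherits(run, "error")) { blew <- TRUE; break }
      keep <- -1L  # first snapshot duplicates the chunk start
      snaps <- c(snaps, run$W_snaps[keep])
      stimes <- c(stimes, run$snap_times[keep])
      W <- run$W; x <- run$x; psb <- run$ps; t <- run$t
      remaining <- remaining - dur
    }
    list(snaps = snaps, stimes = stimes, blowup = blew, t_end = t)
  }
  br_real <- run_branch("real")
  br_imag <- run_branch("imag")

  t_rel_r <- br_real$stimes - burn_in
  t_rel_i <- br_imag$stimes - burn_in
  amp_real <- .amplitude_trace(br_real$snaps, "real", item)
  amp_imag <- .amplitude_trace(br_imag$snaps, "imag", item)

  hl_real <- half_life(t_rel_r, amp_real, baseline = baseline_real)
  hl_imag <- half_life(t_rel_i, amp_imag, baseline = baseline_imag)
  # censor not-decayed half-lives at the observed window so the ratio is a
  # conservative lower bound when the imaginary memory outlives the horizon
  ratio <- min(hl_imag, max(t_rel_i)) / min(hl_real, max(t_rel_r))

  fit_rate <- function(t, a) {
    ok <- a > 1e-10
    if (sum(ok) < 3L) return(NA_real_)
    -unname(stats::coef(stats::lm(log(a[ok]) ~ t[ok]))[2])
  }

  structure(list(rule = rule, N = N, seed = seed, horizon = horizon,
                 noise_on = noise_on,
                 bulk_radius = bulk_radius, a_embed = a_embed,
                 baseline_real = baseline_real, baseline_imag = baseline_imag,
                 times = t_rel_r, times_imag = t_rel_i,
                 amp_real = amp_real, amp_imag = amp_imag,
                 halflife_real = hl_real, halflife_imag = hl_imag,
                 ratio = ratio,
                 blowup_real = br_real$blowup, blowup_imag = br_imag$blowup,
                 t_end_real = br_real$t_end, t_end_imag = br_imag$t_end,
                 decay_rate_real = fit_rate(t_rel_r, amp_real),
                 decay_rate_imag = fit_rate(t_rel_i, amp_imag),
                 snaps_real = br_real$snaps, snap_times = br_real$stimes),
            class = "erosion_report")
}

#' STDP learning experiment
#'
#' Drives the full model (anti-symmetric STDP learning plus a homeostatic
#' rule with noise) with a planar Ornstein-Uhlenbeck stimulus and follows
#' how an imaginary eigenvalue pair aligned with the stimulated plane grows
#' in the connectivity spectrum. Three readouts: the normalized eigenplane
#' overlap of the top imaginary pair with the stimulated plane, the memory
#' strength |Im lambda| as a function of stimulation duration (paired runs
#' with identical streams), and the retention of a first memory while a
#' second plane is learned.
#'
#' @param N network size.
#' @param seed master seed.
#' @param durations stimulation durations to compare (time units).
#' @param rule homeostatic rule active during learning. The default is rate
#'   control, which leaves a subcritical network quiescent so the stimulated
#'   plane is stored cleanly; qualitatively similar results hold across rules.
#' @param amplitude OU stimulus amplitude (see [ou_stimulus()]). The default
#'   keeps the driven rates sub-saturating: strongly saturated rates store a
#'   nonlinearly distorted image of the plane and the eigenplane overlap
#'   degrades.
#' @param settle time before stimulus onset.
#' @param post time simulated after stimulus offset.
#' @param second_plane also learn a second plane after the longest duration?
#' @param g initial connectivity scale; learning runs default to a weak bulk
#'   so the learned pair is read out far outside it.
#' @param stdp an [stdp_config()]; the default anti-symmetric kernel
#'   amplitude is calibrated so that a 100-time-unit stimulus at the default
#'   drive stores a pair clearly outside the bulk.
#' @param dt,eta model constants.
#' @return object of class `learning_report` with per-duration strengths
#'   and overlaps, and (optionally) the two-memory retention readout.
#' @export
learning_experiment <- function(N = 64, seed = 1, durations = c(50, 100, 200),
                                rule = "rate_control", amplitude = 10,
                                settle = 20, post = 20, second_plane = TRUE,
                                g = 0.05, stdp = stdp_config(a_P = 20, a_D = -20),
                                dt = 0.1, eta = 0.01) {
  cfg <- sim_config(N = N, dt = dt, eta = eta, seed = seed, g = g)
  hcfg0 <- homeostasis_config(rule, noise_on = TRUE)

  one_run <- function(dur, two = FALSE) {
    streams <- seed_streams(seed)
    W0 <- random_connectivity(cfg, streams)
    item1 <- sample_memory(streams, N)
    item2 <- sample_memory(streams, N)
    stim1 <- ou_stimulus(item1, settle, settle + dur, dt, streams, amplitude = amplitude)
    input <- stim1
    total <- settle + dur + post
    if (two) {
      stim2 <- ou_stimulus(item2, settle + dur + post, settle + dur + post + dur, dt,
                           streams, amplitude = amplitude)
      input <- compose_inputs(stim1, stim2)
      total <- settle + 2 * (dur + post)
    }
    run <- simulate_network(cfg, W0, duration = total, streams = streams,
                            input_fn = input, hcfg = hcfg0, stdp = stdp,
                            record_every = 0, snap_every = 0)
    list(run = run, item1 = item1, item2 = item2)
  }

  per_dur <- lapply(durations, function(dur) {
    res <- one_run(dur)
    top <- top_imaginary_eigenpair(res$run$W)
    ov <- if (top$absent) 0 else {
      plane_overlap(top$plane[, 1], top$plane[, 2], res$item1$u, res$item1$v)$normalized
    }
    mp <- memory_eigenpair(res$run$W, orthonormalize_item(res$item1))
    list(duration = dur,
         strength = if (mp$absent) 0 else abs(Im(mp$lambda)),
         top_strength = if (top$absent) 0 else abs(Im(top$lambda)),
         top_overlap = ov)
  })

  two_mem <- NULL
  if (second_plane) {
    dur <- durations[length(durations) %/% 2 + 1L]
    res <- one_run(dur, two = TRUE)
    mp1 <- memory_eigenpair(res$run$W, orthonormalize_item(res$item1))
    mp2 <- memory_eigenpair(res$run$W, orthonormalize_item(res$item2))
    two_mem <- list(duration = dur,
                    strength1 = if (mp1$absent) 0 else abs(Im(mp1$lambda)),
                    overlap1 = mp1$overlap,
                    strength2 = if (mp2$absent) 0 else abs(Im(mp2$lambda)),
                    overlap2 = mp2$overlap)
  }

  structure(list(N = N, seed = seed, rule = rule, amplitude = amplitude,
                 durations = durations,
                 strengths = vapply(per_dur, `[[`, numeric(1), "strength"),
                 top_overlaps = vapply(per_dur, `[[`, numeric(1), "top_overlap"),
                 top_strengths = vapply(per_dur, `[[`, numeric(1), "top_strength"),
                 two_memory = two_mem),
            class = "learning_report")
}

#' Associative-retrieval experiment with fixed connectivity
#'
#' With plasticity frozen, embeds M memory planes (gamma-augmented, so each
#' carries a persistent limit cycle) and probes retrieval: (a) convergence
#' of trajectories started inside and outside the orbit of a single memory
#' to the same closed orbit; (b) with M planes, cueing one plane and
#' comparing the radial overlaps r_k; (c) cueing a random, non-embedded
#' plane.
#'
#' @param N network size.
#' @param M number of embedded planes for the selectivity probe.
#' @param rho memory strength.
#' @param gamma real-part coefficient (> 1 for persistent orbits).
#' @param seed master seed.
#' @param duration integration time per probe.
#' @param dt integration step.
#' @param sel_window time window (after the cue) over which the per-plane
#'   radial overlaps are averaged for the selectivity readout. Retrieval
#'   selectivity in this model is transient: on the winner's orbit the
#'   small-signal gain of every other plane is exactly marginal (for
#'   Gaussian patterns and an odd nonlinearity, Stein's identity equates
#'   the large-signal and small-signal gains), so distractor overlaps grow
#'   from their nonlinear-harmonic seeds and the network eventually settles
#'   into a multi-plane coexistence state. The default window reads out the
#'   transient phase.
#' @return object of class `retrieval_report`: orbit amplitudes from the two
#'   initial conditions and their relative difference, windowed radial
#'   overlaps per plane under a plane-1 cue, and the novel-cue response
#'   ratio.
#' @export
retrieval_experiment <- function(N = 512, M = 5, rho = 4, gamma = 1.5, seed = 1,
                                 duration = 100, dt = 0.1, sel_window = c(5, 20)) {
  streams <- seed_streams(seed)
  cfg <- sim_config(N = N, dt = dt, seed = seed)
  item <- sample_memory(streams, N, rho = rho, gamma = gamma)
  W1 <- embed_imaginary(matrix(0, N, N), item)

  start_on_plane <- function(it, r0) sqrt(N) * r0 * it$u
  amp_of <- function(x0, W, it) {
    traj <- run_trajectory(x0, W, NULL, duration, cfg, project_items = list(it))
    orbit_amplitude(traj$proj[[1]][, 1:2])
  }
  amp_in <- amp_of(start_on_plane(item, 0.2), W1, item)
  amp_out <- amp_of(start_on_plane(item, 3), W1, item)
  orbit_rel_diff <- abs(amp_in - amp_out) / max(amp_in, amp_out)

  items <- lapply(seq_len(M), function(k) sample_memory(streams, N, rho = rho, gamma = gamma))
  WM <- build_bank_connectivity(memory_bank(items), gamma = gamma)
  trajM <- run_trajectory(start_on_plane(items[[1]], 1), WM, NULL, duration, cfg,
                          project_items = items)
  win <- trajM$times >= sel_window[1] & trajM$times <= sel_window[2]
  last <- trajM$times > duration * 0.8
  r_window <- vapply(trajM$proj, function(p) mean(p[win, "r"]), numeric(1))
  r_final <- vapply(trajM$proj, function(p) mean(p[last, "r"]), numeric(1))

  novel <- sample_memory(streams, N, rho = rho, gamma = gamma)
  trajN <- run_trajectory(start_on_plane(novel, 1), WM, NULL, duration, cfg,
                          project_items = c(items, list(novel)))
  r_novel <- vapply(trajN$proj, function(p) mean(p[win, "r"]), numeric(1))

  structure(list(N = N, M = M, rho = rho, gamma = gamma, seed = seed,
                 amp_inside = amp_in, amp_outside = amp_out,
                 orbit_rel_diff = orbit_rel_diff,
                 sel_window = sel_window,
                 r_window = r_window, r_final = r_final,
                 selectivity = r_window[1] / max(r_window[-1]),
                 selectivity_final = r_final[1] / max(r_final[-1]),
                 r_novel = r_novel,
                 novel_response_ratio = max(r_novel) / r_window[1]),
            class = "retrieval_report")
}

#' Full memory life cycle: learn, retain, retrieve
#'
#' Sequentially learns two memory planes with the STDP rule under
#' homeostasis and noise, retains them, then cues each plane (and a novel
#' one) with brief retrieval pulses, recording plane overlaps r_1, r_2, r_3,
#' example synaptic weights, eigenvalue snapshots, and the relative
#' contributions of activity-dependent vs spontaneous plasticity (temporal
#' averages of \eqn{\frac1{N^2}\sum_{ij}|\Delta_{ij}|}).
#'
#' @param N network size (default 64 for routine runs).
#' @param seed master seed.
#' @param rule homeostatic rule. Rate control (the reference rule for the
#'   life-cycle dynamics) keeps the network quiescent between events;
#'   decorrelation is the reference rule for contribution accounting.
#' @param amplitude OU stimulus amplitude during learning.
#' @param stdp an [stdp_config()] for the learning term.
#' @param stim_dur duration of each learning stimulus.
#' @param dt,eta,g model constants.
#' @return object of class `lifecycle_report` with the protocol schedule,
#'   projection traces, weight traces, eigen snapshots, retrieval readouts
#'   and a `contribution` component (class `contribution_report`):
#'   mean_abs_activity_dependent, mean_abs_spontaneous, ratio.
#' @export
lifecycle_experiment <- function(N = 64, seed = 1, rule = "rate_control",
                                 amplitude = 10, stim_dur = 100,
                                 stdp = stdp_config(a_P = 20, a_D = -20),
                                 dt = 0.1, eta = 0.01, g = 0.05) {
  cfg <- sim_config(N = N, dt = dt, eta = eta, seed = seed, g = g)
  streams <- seed_streams(seed)
  hcfg <- homeostasis_config(rule, noise_on = TRUE)
  W0 <- random_connectivity(cfg, streams)
  item1 <- sample_memory(streams, N)
  item2 <- sample_memory(streams, N)
  item3 <- sample_memory(streams, N)  # novel plane, never learned

  t_stim1 <- 20
  t_stim2 <- t_stim1 + stim_dur + 20
  t_ret_end <- t_stim2 + stim_dur + 100
  t1 <- t_ret_end; t2 <- t1 + 40; t3 <- t2 + 40
  t_end <- t3 + 40

  stim1 <- ou_stimulus(item1, t_stim1, t_stim1 + stim_dur, dt, streams, amplitude = amplitude)
  stim2 <- ou_stimulus(item2, t_stim2, t_stim2 + stim_dur, dt, streams, amplitude = amplitude)
  cue1 <- retrieval_cue(item1, t1)
  cue2 <- retrieval_cue(item2, t2)
  cue3 <- retrieval_cue(item3, t3)
  input <- compose_inputs(stim1, stim2, cue1, cue2, cue3)

  wt_idx <- cbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  run <- simulate_network(cfg, W0, duration = t_end, streams = streams,
                          input_fn = input, hcfg = hcfg, stdp = stdp,
                          project_items = list(item1, item2, item3),
                          record_every = dt, snap_every = 10,
                          weight_trace = wt_idx)

  window_max <- function(proj_idx, from, to) {
    w <- run$times >= from & run$times <= to
    max(run$proj[[proj_idx]][w, "r"])
  }
  retr <- list(
    r1_at_t1 = window_max(1, t1, t1 + 10), r2_at_t1 = window_max(2, t1, t1 + 10),
    r2_at_t2 = window_max(2, t2, t2 + 10), r1_at_t2 = window_max(1, t2, t2 + 10),
    r3_at_t3 = window_max(3, t3, t3 + 10)
  )
  # oscillation readout on the post-pulse ringing (the pulse itself is
  # broad-band and would dominate the periodogram)
  w_freq <- run$times > t1 + 2 & run$times <= t1 + 22
  freq1 <- dominant_frequency(run$proj[[1]][w_freq, "p_u"], dt)

  mp1 <- memory_eigenpair(run$W, orthonormalize_item(item1))
  mp2 <- memory_eigenpair(run$W, orthonormalize_item(item2))

  contribution <- structure(
    list(mean_abs_activity_dependent = run$contrib$activity_dependent,
         mean_abs_spontaneous = run$contrib$noise,
         mean_abs_learning = run$contrib$learning,
         mean_abs_homeostatic = run$contrib$homeostatic,
         ratio = run$contrib$activity_dependent / run$contrib$noise),
    class = "contribution_report")

  structure(list(N = N, seed = seed, rule = rule,
                 schedule = list(stim1 = c(t_stim1, t_stim1 + stim_dur),
                                 stim2 = c(t_stim2, t_stim2 + stim_dur),
                                 cues = c(t1, t2, t3), t_end = t_end),
                 times = run$times, proj = run$proj,
                 weight_traces = run$weight_traces,
                 snap_times = run$snap_times, W_snaps = run$W_snaps,
                 retrieval = retr, retrieval_frequency = freq1,
                 strength1 = if (mp1$absent) 0 else abs(Im(mp1$lambda)),
                 strength2 = if (mp2$absent) 0 else abs(Im(mp2$lambda)),
                 contribution = contribution),
            class = "lifecycle_report")
}

#' Erosion under structural sparsity
#'
#' Repeats the paired erosion experiment at several structural connection
#' densities (same master seed, so the density-1 run reproduces the dense
#' experiment exactly) and reports the realized post-embedding imaginary
#' amplitude and the half-life ratio at each density.
#'
#' @param densities vector of densities in (0, 1].
#' @param N network size.
#' @param seed master seed.
#' @param rule homeostatic rule.
#' @param horizon tracking window per run.
#' @param ... further arguments passed to [erosion_experiment()].
#' @return object of class `sparsity_report`: per-density imaginary
#'   amplitudes, half-lives and ratios.
#' @export
sparsity_sweep <- function(densities = c(1, 0.5, 0.25), N = 64, seed = 1,
                           rule = "rate_control", horizon = 2000, ...) {
  reports <- lapply(densities, function(d) {
    erosion_experiment(rule, N = N, seed = seed, horizon = horizon, density = d, ...)
  })
  structure(list(densities = densities,
                 imag_amplitude = vapply(reports, function(r) r$amp_imag[1], numeric(1)),
                 halflife_real = vapply(reports, `[[`, numeric(1), "halflife_real"),
                 halflife_imag = vapply(reports, `[[`, numeric(1), "halflife_imag"),
                 ratio = vapply(reports, `[[`, numeric(1), "ratio"),
                 reports = reports),
            class = "sparsity_report")
}

## ---------------------------------------------------------------------------
## Capacity
## ---------------------------------------------------------------------------

.capacity_trial_antisym <- function(N, M, streams, steps, corrupt, avg_last) {
  avg_last <- min(avg_last, steps)
  items <- lapply(seq_len(M), function(k) {
    u <- stream_rnorm(streams, "trials", N, sd = 1 / sqrt(N))
    v <- stream_rnorm(streams, "trials", N, sd = 1 / sqrt(N))
    memory_item(u, v)
  })
  W <- build_bank_connectivity(memory_bank(items), gamma = 0)
  net <- discrete_net(W, nonlinearity("sign"))
  x0 <- sqrt(N) * items[[1]]$u
  z <- stream_rnorm(streams, "trials", N)
  x0 <- x0 + corrupt * sqrt(sum(x0^2)) * z / sqrt(sum(z^2))
  res <- run_discrete(net, x0, steps, project_items = items)
  keep <- (steps - avg_last + 1L):steps
  rel <- vapply(keep, function(k) {
    rk <- vapply(res$proj, function(p) p[k, "r"], numeric(1))
    rk[1] / sqrt(sum(rk^2))
  }, numeric(1))
  mean(rel)
}

.capacity_trial_hopfield <- function(N, M, streams, steps, corrupt, avg_last) {
  avg_last <- min(avg_last, steps)
  hb <- hopfield_baseline(N, M, streams)
  xi <- hb$patterns
  x <- xi[, 1]
  nflip <- round(corrupt * N)
  if (nflip > 0) {
    flip <- stream_eval(streams, "trials", function() sample.int(N, nflip))
    x[flip] <- -x[flip]
  }
  m_hist <- matrix(NA_real_, steps, M)
  for (k in seq_len(steps)) {
    x <- discrete_step(hb$net, x)
    m_hist[k, ] <- abs(as.vector(crossprod(xi, x))) / N
  }
  keep <- (steps - avg_last + 1L):steps
  rel <- m_hist[keep, 1] / sqrt(rowSums(m_hist[keep, , drop = FALSE]^2))
  mean(rel)
}

#' Associative-memory capacity of the anti-symmetric model vs Hopfield
#'
#' Measures the critical memory load of the discrete-time anti-symmetric
#' (planar limit-cycle) model and of the symmetric Hopfield baseline with an
#' identical protocol: cue pattern 1 with 10 percent corruption, run the
#' synchronous sign dynamics, and call retrieval successful when the
#' time-averaged relative overlap with the target
#' (\eqn{r_1/\sqrt{\sum_k r_k^2}}, pattern overlaps for Hopfield) exceeds
#' `threshold` over the final `avg_last` steps. The critical load is the
#' largest load with success rate at least 1/2, refined by linear
#' interpolation of the success-rate crossing. Planar memories occupy two
#' dimensions each, so the anti-symmetric load is reported as 2M/N
#' (M/N is also returned).
#'
#' @param N_values network sizes to test.
#' @param loads grid of loads (2M/N for the planar model, M/N for Hopfield).
#' @param trials trials per load.
#' @param steps synchronous updates per trial.
#' @param corrupt cue corruption fraction.
#' @param threshold success threshold on the relative overlap.
#' @param avg_last number of final steps averaged.
#' @param seed master seed.
#' @return object of class `capacity_report`: per-N critical loads for both
#'   models and the success-rate tables.
#' @export
capacity_experiment <- function(N_values = c(128, 256, 512),
                                loads = seq(0.04, 0.24, by = 0.02),
                                trials = 20, steps = 100, corrupt = 0.1,
                                threshold = 0.9, avg_last = 50, seed = 1) {
  run_model <- function(N, model) {
    rates <- vapply(loads, function(al) {
      M <- max(1L, as.integer(round(if (model == "antisym") al * N / 2 else al * N)))
      succ <- vapply(seq_len(trials), function(tr) {
        streams <- seed_streams(.substream_seed(seed, 1000 * N + 100 * round(al * 1000) + tr))
        rel <- if (model == "antisym") {
          .capacity_trial_antisym(N, M, streams, steps, corrupt, avg_last)
        } else {
          .capacity_trial_hopfield(N, M, streams, steps, corrupt, avg_last)
        }
        rel > threshold
      }, logical(1))
      mean(succ)
    }, numeric(1))
    crit <- .critical_load(loads, rates)
    list(rates = rates, critical = crit)
  }
  res <- lapply(N_values, function(N) {
    list(N = N,
         antisym = run_model(N, "antisym"),
         hopfield = run_model(N, "hopfield"))
  })
  structure(list(N_values = N_values, loads = loads, trials = trials,
                 results = res,
                 critical_antisym = vapply(res, function(r) r$antisym$critical, numeric(1)),
                 critical_hopfield = vapply(res, function(r) r$hopfield$critical, numeric(1))),
            class = "capacity_report")
}

.critical_load <- function(loads, rates) {
  ok <- which(rates >= 0.5)
  if (length(ok) == 0L) return(loads[1] / 2)
  j <- max(ok)
  if (j == length(loads)) return(loads[j])
  # interpolate the 0.5 crossing between the last success and first failure
  l1 <- loads[j]; l2 <- loads[j + 1L]
  r1 <- rates[j]; r2 <- rates[j + 1L]
  if (r1 == r2) return(l1)
  l1 + (r1 - 0.5) / (r1 - r2) * (l2 - l1)
}
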