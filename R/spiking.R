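#' Configuration for a spiking network simulation
#'
#' Assembles everything the clock-driven conductance-LIF simulator needs:
#' physiological constants and tuned conductances (rescaled to the simulated
#' population sizes, `g = g_tilde / N_pre`), the recurrent kernel (optionally
#' degraded by a frozen-noise realization, with `1/p` rescaling), leak
#' offsets, and the stimulation protocol.
#'
#' Protocols: `"cue"` runs `t_initial` of spontaneous activity, then a
#' two-phase localized cue (0.5 s at `cue_rate_1`, 0.5 s at `cue_rate_2`,
#' onto a fraction of excitatory neurons centered at `cue_phi`, with
#' synapses scaled by `g_signal`); `"uncued"` runs spontaneously;
#' `"reset_after_cue"` appends a brief strong four-point uniform-ish input
#' that drives the network back to the non-selective state.
#'
#' @param par tuned [lif_params()].
#' @param stp an [stp_params()] object.
#' @param N_E,N_I simulated population sizes (conductances rescale
#'   automatically).
#' @param t_max total simulated time (s).
#' @param protocol `"cue"`, `"uncued"` or `"reset_after_cue"`.
#' @param cue_phi cue center (rad).
#' @param t_initial spontaneous interval before the cue (s).
#' @param cue_rate_1,cue_rate_2 cue Poisson rates (Hz).
#' @param g_signal cue synaptic scale.
#' @param reset_at time of the reset input, for `"reset_after_cue"` (s).
#' @param realization optional [sample_frozen()] connectivity/jitter
#'   realization (leak realizations supply `delta_L`).
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param stp_frozen freeze the synapses at `u = U`, `x = 1` (linear
#'   transmission control).
#' @param init_bump optional [solve_bump()] result (at size `N_E`): the
#'   synaptic state is initialized on the bump instead of the basal state.
#' @param g_EE_factor multiplicative correction on the recurrent excitatory
#'   conductance, compensating the measured bias of the diffusion
#'   approximation at the bump operating point (the Monte-Carlo rate of the
#'   conductance neuron at the bump-top drive is about 6% below the
#'   rate-reduction prediction; without compensation the simulated bump is
#'   marginally subcritical at reduced scale).
#' @return object of class `spiking_config` (a list).
#' @export
spiking_config <- function(par, stp, N_E = 200L, N_I = 50L, t_max = 8,
                           protocol = c("cue", "uncued", "reset_after_cue"),
                           cue_phi = 0, t_initial = 0.5,
                           cue_rate_1 = 3000, cue_rate_2 = 1500,
                           g_signal = 0.5, reset_at = NULL,
                           realization = NULL, dt = 1e-4, seed = 1L,
                           stp_frozen = FALSE, init_bump = NULL,
                           g_EE_factor = 1.06) {
  protocol <- match.arg(protocol)
  N_E <- as.integer(N_E); N_I <- as.integer(N_I)
  geom <- ring_geometry(N_E)
  W <- ring_kernel(geom, par$w_plus, par$kernel_width)
  delta_L <- rep(0, N_E)
  if (!is.null(realization)) {
    if (realization$spec$kind == "leak") {
      stopifnot(realization$N == N_E)
      delta_L <- realization$delta_L
    } else {
      stopifnot(realization$N == N_E)
      W <- perturbed_weights(W, realization)
    }
  }
  stim <- NULL; target <- NULL
  if (protocol %in% c("cue", "reset_after_cue")) {
    frac <- if (stp$U <= 0.1) 0.18 else 0.2
    n_cue <- round(frac * N_E)
    d <- abs(circ_diff(geom$theta, cue_phi))
    cue_set <- rank(d, ties.method = "first") <= n_cue
    stim <- rbind(c(t_initial, t_initial + 0.5, cue_rate_1, g_signal),
                  c(t_initial + 0.5, t_initial + 1.0, cue_rate_2, g_signal))
    target <- cbind(cue_set, cue_set)
  }
  if (protocol == "reset_after_cue") {
    if (is.null(reset_at)) reset_at <- t_initial + 1.0 + 2.0
    anchors <- seq(-pi, pi, length.out = 5L)[1:4]
    rs <- rep(FALSE, N_E)
    for (a in anchors) {
      d <- abs(circ_diff(geom$theta, a))
      rs <- rs | rank(d, ties.method = "first") <= max(1L, round(N_E / 40))
    }
    stim <- rbind(stim, c(reset_at, reset_at + 0.5, 1500, 2))
    target <- cbind(target, rs)
  }
  if (is.null(stim)) {
    stim <- matrix(0, 0, 4)
    target <- matrix(FALSE, N_E, 0)
  }
  structure(list(
    N_E = N_E, N_I = N_I, dt = dt, T = t_max,
    V_L = par$V_L, V_E = par$V_E, V_I = par$V_I,
    V_thr = par$V_thr, V_res = par$V_res,
    Cm_E = par$Cm_E, Cm_I = par$Cm_I, gL_E = par$gL_E, gL_I = par$gL_I,
    tau_ref_E = par$tau_ref_E, tau_ref_I = par$tau_ref_I,
    tau_ext = par$tau_ext, tau_E = par$tau_E, tau_I = par$tau_I,
    g_ext_E = par$g_ext_E, g_ext_I = par$g_ext_I,
    g_EE = g_EE_factor * par$g_EE / N_E, g_EI = par$g_EI / N_I,
    g_IE = par$g_IE / N_E, g_II = par$g_II / N_I,
    rate_ext = par$N_ext * par$nu_ext,
    U = stp$U, tau_u = stp$tau_u, tau_x = stp$tau_x,
    stp_frozen = isTRUE(stp_frozen),
    W_EE = W, delta_L = delta_L,
    init_sj = if (is.null(init_bump)) {
      rep(par$tau_E * poisson_mean_ux(0.5, stp) * 0.5, N_E)
    } else init_bump$s0,
    init_uj = if (is.null(init_bump)) rep(stp$U, N_E) else init_bump$u0,
    init_xj = if (is.null(init_bump)) rep(1, N_E) else init_bump$x0,
    init_sIE = if (is.null(init_bump)) N_E * par$tau_E * 0.5 else
      N_E * par$tau_E * mean(init_bump$phi0),
    init_sII = N_I * par$tau_I * if (is.null(init_bump)) 3 else
      attr(par, "nu_I_bump") %||% 3,
    init_sEI = N_I * par$tau_I * if (is.null(init_bump)) 3 else
      attr(par, "nu_I_bump") %||% 3,
    stim = stim, stim_target = target,
    t_initial = t_initial, t_off = t_initial + 1.0,
    protocol = protocol, seed = as.integer(seed)),
    class = "spiking_config")
}

#' Simulate the spiking network
#'
#' Runs the clock-driven conductance-LIF simulation and post-processes the
#' excitatory spikes into filtered rates and a bump-center trajectory
#' (sampled after cue offset).
#'
#' @param config a [spiking_config()].
#' @param sample_dt sampling resolution of the filtered rates (s).
#' @param kernel_tau exponential filter time constant (s).
#' @return list with `spikes_E`, `spikes_I` (data.frames `neuron`, `t`),
#'   `times` (s, from cue offset onward), `center` (rad), `maxrate` (Hz,
#'   population max of filtered rates), `rates` (times x neurons), and the
#'   `config`.
#' @export
simulate_spiking <- function(config, sample_dt = 0.005, kernel_tau = 0.1) {
  set.seed(config$seed)
  raw <- spiking_cpp(unclass(config))
  t0 <- config$t_off
  rates <- rates_from_spikes(raw$spikes_E, config$N_E, config$T,
                             kernel_tau = kernel_tau, sample_dt = sample_dt,
                             t_min = 0)
  times_all <- attr(rates, "times")
  sel <- times_all >= t0
  R <- rates[sel, , drop = FALSE]
  mx <- apply(R, 1L, max)
  ctr <- rep(NA_real_, nrow(R))
  ok <- mx > 0
  if (any(ok)) ctr[ok] <- center_phase(R[ok, , drop = FALSE])
  list(spikes_E = raw$spikes_E, spikes_I = raw$spikes_I,
       times = times_all[sel] - t0, center = ctr, maxrate = mx,
       rates = R, config = config)
}

#' Mean rates of a spiking run over a window
#'
#' @param sim a [simulate_spiking()] result.
#' @param window time window (s, relative to cue offset).
#' @return list with `nu_E` (per-neuron mean rates, Hz) and `nu_I`
#'   (population mean, Hz).
#' @export
spiking_mean_rates <- function(sim, window = NULL) {
  cfg <- sim$config
  if (is.null(window)) window <- c(0, max(sim$times))
  w_abs <- window + cfg$t_off
  dur <- diff(window)
  spE <- sim$spikes_E
  nE <- tabulate(spE$neuron[spE$t >= w_abs[1] & spE$t < w_abs[2]],
                 nbins = cfg$N_E)
  spI <- sim$spikes_I
  nI <- sum(spI$t >= w_abs[1] & spI$t < w_abs[2])
  list(nu_E = nE / dur, nu_I = nI / (dur * cfg$N_I))
}

#' End-to-end validation of the theory against the spiking network
#'
#' Runs repeated spiking delay periods with the network initialized in the
#' stationary bump state rotated to each cue position (at reduced scale the
#' Poisson-cue handoff is destabilized by the depression-depletion overshoot
#' at cue offset, and the theory assumes the state starts on the attractor
#' manifold anyway), excludes lost bumps, estimates the center diffusion,
#' and compares it with the theoretical diffusion strength scaled to the
#' simulated size.
#'
#' @param ref a [reference_network()] result (coefficients at `N_ref`).
#' @param n_reps repetitions.
#' @param duration delay duration after cue offset (s).
#' @param N_E,N_I simulated sizes.
#' @param realization optional frozen realization at size `N_E`.
#' @param seed base seed; repetition `k` uses `seed + k`.
#' @param cue_positions initial cue angles, recycled over repetitions.
#' @param discard initial delay discarded by the diffusion estimator (s).
#' @param dt integration step (s).
#' @param smooth_window window (s) for smoothing the population-max rate
#'   before applying the collapse threshold; at reduced network size the
#'   instantaneous maximum fluctuates about twice as strongly as at full
#'   size, so the collapse rule is evaluated on a moving average.
#' @return list with `B_measured` (a [estimate_diffusion()] result),
#'   `B_predicted` (rad^2/s at `N_E`, from the reference rate-approximation
#'   bump), `B_predicted_measured_shape` (from the bump shape measured in
#'   the kept repetitions), `ratio`, `ratio_measured_shape`, `n_kept`,
#'   `mean_profile`, `trajectories`.
#' @export
validate_against_theory <- function(ref, n_reps = 50L, duration = 5,
                                    N_E = 200L, N_I = 50L,
                                    realization = NULL, seed = 1L,
                                    cue_positions = seq(-pi, pi,
                                                        length.out = 11L)[1:10],
                                    discard = 0.5, dt = 2e-5,
                                    smooth_window = 0.5) {
  stp <- ref$stp
  th <- attractor_theory(ref$bump)
  B_pred <- scale_with_N(th$B, 0, 0, N_ref = ref$bump$N, N = N_E)$B
  W <- ring_kernel(ring_geometry(N_E), ref$par$w_plus, ref$par$kernel_width)
  b0 <- solve_bump(W, ref$gain, stp,
                   init = generalized_gaussian_profile(ring_geometry(N_E)),
                   method = "newton", tol = 1e-8)
  trajs <- NULL; times <- NULL; kept <- 0L
  prof_sum <- NULL; prof_n <- 0L
  for (k in seq_len(n_reps)) {
    cue_phi <- cue_positions[((k - 1L) %% length(cue_positions)) + 1L]
    bk <- rotate_bump(b0, round(cue_phi / (2 * pi / N_E)))
    cfg <- spiking_config(ref$par, stp, N_E = N_E, N_I = N_I,
                          t_max = duration, protocol = "uncued",
                          realization = realization, seed = seed + k,
                          dt = dt, init_bump = bk)
    cfg$t_off <- 0
    sim <- simulate_spiking(cfg)
    w <- max(1L, round(smooth_window / diff(sim$times[1:2])))
    mx_smooth <- as.numeric(stats::filter(sim$maxrate, rep(1 / w, w),
                                          sides = 2))
    # a transient collapse/re-nucleation can slip past the rate threshold
    # but shows up as a center displacement no drifting bump can produce
    wj <- max(1L, round(0.1 / diff(sim$times[1:2])))
    nts <- length(sim$center)
    jumps <- abs(circ_diff(sim$center[(wj + 1):nts], sim$center[1:(nts - wj)]))
    if (exclude_lost_bumps(min(mx_smooth, na.rm = TRUE)) &&
        max(jumps, na.rm = TRUE) < pi / 2) {
      trajs <- rbind(trajs, sim$center)
      times <- sim$times
      kept <- kept + 1L
      # rectified mean profile: rotate each sample by its (fractional)
      # center estimate via an FFT phase shift, so averaging does not smear
      # the flanks
      sel <- which(sim$times >= discard & is.finite(sim$center))
      kf <- c(0:(N_E / 2), -(N_E / 2 - 1):-1); kf[N_E / 2 + 1] <- 0
      for (i in sel) {
        sh <- sim$center[i] / (2 * pi / N_E)
        f <- stats::fft(sim$rates[i, ])
        prof <- Re(stats::fft(f * exp(2i * pi * kf * sh / N_E),
                              inverse = TRUE)) / N_E
        prof_sum <- if (is.null(prof_sum)) prof else prof_sum + prof
        prof_n <- prof_n + 1L
      }
    }
  }
  if (kept == 0L) stop("all repetitions lost the bump state")
  est <- estimate_diffusion(trajs, times, discard = discard)
  # the FFT phase-shift rectification can leave small negative ringing in
  # the silent region; rates are non-negative by construction
  mean_profile <- pmax(prof_sum / prof_n, 0)
  b_meas <- bump_from_profile(mean_profile, W, ref$gain, stp)
  B_pred_meas <- attractor_theory(b_meas)$B
  list(B_measured = est, B_predicted = B_pred,
       B_predicted_measured_shape = B_pred_meas,
       ratio = est$slope / B_pred,
       ratio_measured_shape = est$slope / B_pred_meas,
       n_kept = kept, mean_profile = mean_profile,
       trajectories = structure(list(times = times, phi = trajs),
                                class = "trajectory_set"))
}
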