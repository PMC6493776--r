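#' Effective weights under a frozen-noise realization
#'
#' Applies a connectivity mask (with `1/p` rescaling, so the mean drive is
#' unchanged) and/or additive weight jitter to a homogeneous kernel.
#'
#' @param weights homogeneous weight matrix.
#' @param realization a [sample_frozen()] result, or `NULL` (no change).
#' @return perturbed weight matrix.
#' @export
perturbed_weights <- function(weights, realization = NULL) {
  if (is.null(realization)) return(weights)
  if (realization$spec$kind == "leak") return(weights)
  W <- weights
  if (!is.null(realization$jitter)) W <- W + realization$jitter
  W * realization$mask / realization$spec$p
}

gain_cpp_spec <- function(gain) {
  if (identical(gain$label, "softplus"))
    list(type = 0L, pars = gain$pars)
  else if (identical(gain$label, "threshold_quadratic"))
    list(type = 1L, pars = gain$pars)
  else stop("the stochastic rate simulator supports the analytic toy gains ",
            "(softplus, threshold_quadratic) only")
}

#' Simulate the stochastic rate network
#'
#' Euler-Maruyama integration of the full `3N`-dimensional synaptic system
#' with multiplicative Poisson-rate noise (the three synaptic equations of
#' each neuron share one noise increment scaled by `sqrt(phi_i)`); with
#' `noise = FALSE` the deterministic rate dynamics are integrated.  The
#' simulation starts from the steady bump state, optionally rotated and
#' perturbed by a frozen-noise realization.
#'
#' @param bump a [solve_bump()] result for the homogeneous network (toy
#'   gain).
#' @param duration simulated time (s).
#' @param dt integration step (s).
#' @param noise include the stochastic terms.
#' @param seed RNG seed (`NULL` to continue the current stream).
#' @param realization optional [sample_frozen()] result perturbing the
#'   weights.
#' @param J_offset optional per-neuron additive input (frozen "leak-like"
#'   heterogeneity for rate models).
#' @param center0 initial bump center (rad); the steady profile is rotated
#'   to the nearest grid point.
#' @param sample_dt sampling resolution of the recorded center (s).
#' @return list with `times`, `center` (rad), `maxrate` (Hz), `phi_final`.
#' @export
simulate_rate <- function(bump, duration, dt = 5e-4, noise = TRUE,
                          seed = NULL, realization = NULL, J_offset = 0,
                          center0 = bump$center, sample_dt = 0.01) {
  gs <- gain_cpp_spec(bump$gain)
  N <- bump$N
  k0 <- round((center0 - bump$center) / (2 * pi / N))
  b <- if (k0 != 0) rotate_bump(bump, k0) else bump
  Weff <- perturbed_weights(bump$weights, realization) / N
  if (length(J_offset) == 1L) J_offset <- rep(J_offset, N)
  if (!is.null(seed)) set.seed(seed)
  sample_every <- max(1L, round(sample_dt / dt))
  n_steps <- round(duration / dt)
  res <- rate_sde_cpp(Weff, J_offset, b$s0, b$u0, b$x0,
                      gs$type, gs$pars,
                      bump$stp$U, bump$stp$tau_u, bump$stp$tau_x,
                      bump$stp$tau_s,
                      dt, as.integer(n_steps), as.integer(sample_every),
                      isTRUE(noise))
  res
}

#' Deterministic drift velocity of a perturbed rate network
#'
#' Measures the bump-center velocity of the noise-free rate network under a
#' frozen perturbation, from a window after the initial shape relaxation.
#' This is the simulation-side ground truth for the predicted drift field.
#'
#' @inheritParams simulate_rate
#' @param centers initial center angles to probe (rad).
#' @param t_relax relaxation interval excluded from the velocity fit (s).
#' @param t_measure measurement interval (s).
#' @return data.frame with `center` (requested angle) and `v` (rad/s).
#' @export
measure_drift_deterministic <- function(bump, realization = NULL,
                                        J_offset = 0,
                                        centers = bump$theta,
                                        t_relax = 0.5, t_measure = 0.5,
                                        dt = 5e-4) {
  v <- vapply(centers, function(c0) {
    tr <- simulate_rate(bump, t_relax + t_measure, dt = dt, noise = FALSE,
                        realization = realization, J_offset = J_offset,
                        center0 = c0, sample_dt = t_measure / 4)
    i1 <- which.min(abs(tr$times - t_relax))
    i2 <- length(tr$times)
    circ_diff(tr$center[i2], tr$center[i1]) / (tr$times[i2] - tr$times[i1])
  }, numeric(1))
  data.frame(center = centers, v = v)
}
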