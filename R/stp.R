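#' Short-term plasticity parameters
#'
#' Container for the Tsodyks-Markram model of short-term synaptic facilitation
#' and depression. `U` is the baseline release fraction (a presynaptic spike
#' from a fully recovered synapse releases a fraction `U` of its resources);
#' small `U` means strong facilitation, `U = 1` none. `tau_u` is the recovery
#' time of the facilitation variable, `tau_x` the recovery time from
#' depression, and `tau_s` the decay time of the postsynaptic activation
#' (a slow, NMDA-like synaptic trace in the networks modelled here).
#'
#' All times are in seconds; `tau_x = 0` is the exact no-depression limit
#' (the resource variable is then identically 1).
#'
#' @param U baseline release fraction, in (0, 1].
#' @param tau_u facilitation recovery time constant (s, > 0).
#' @param tau_x depression recovery time constant (s, >= 0).
#' @param tau_s synaptic activation decay time constant (s, > 0).
#' @return An object of class `stp_params`.
#' @examples
#' stp_params(U = 0.1, tau_u = 0.65, tau_x = 0.15)
#' @export
stp_params <- function(U, tau_u, tau_x, tau_s = 0.1) {
  stopifnot(is.numeric(U), length(U) == 1L, U > 0, U <= 1)
  stopifnot(is.numeric(tau_u), length(tau_u) == 1L, tau_u > 0)
  stopifnot(is.numeric(tau_x), length(tau_x) == 1L, tau_x >= 0)
  stopifnot(is.numeric(tau_s), length(tau_s) == 1L, tau_s > 0)
  structure(list(U = U, tau_u = tau_u, tau_x = tau_x, tau_s = tau_s),
            class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  cat(sprintf(
    "Short-term plasticity: U = %g, tau_u = %g ms, tau_x = %g ms, tau_s = %g ms\n",
    x$U, 1000 * x$tau_u, 1000 * x$tau_x, 1000 * x$tau_s))
  invisible(x)
}

#' Time derivatives of the synaptic variables
#'
#' Right-hand side of the rate-based facilitation/depression dynamics for one
#' synapse driven at a (non-negative) presynaptic firing rate:
#' \deqn{\dot s = -s/\tau_s + u x \phi, \quad
#'       \dot u = -(u - U)/\tau_u + U (1 - u)\phi, \quad
#'       \dot x = -(x - 1)/\tau_x - u x \phi.}
#' With `tau_x = 0` the depression variable is clamped at 1 (`xdot = 0`).
#'
#' @param state list or numeric vector with components `s`, `u`, `x`.
#' @param rate presynaptic firing rate (Hz, >= 0); may be a vector matched to
#'   vector-valued states.
#' @param params an [stp_params()] object.
#' @return list with components `s`, `u`, `x` holding the time derivatives.
#' @export
stp_derivatives <- function(state, rate, params) {
  if (any(rate < 0)) stop("firing rate must be non-negative")
  s <- state$s; u <- state$u; x <- state$x
  ds <- -s / params$tau_s + u * x * rate
  du <- -(u - params$U) / params$tau_u + params$U * (1 - u) * rate
  dx <- if (params$tau_x > 0) -(x - 1) / params$tau_x - u * x * rate else 0 * x
  list(s = ds, u = du, x = dx)
}

#' Steady state of the synaptic variables at constant rate
#'
#' Closed-form fixed point of the facilitation/depression dynamics for a
#' synapse driven at a constant presynaptic rate:
#' \deqn{u_0 = U\frac{1+\tau_u\nu}{1+U\tau_u\nu},\quad
#'       x_0 = \frac{1+U\tau_u\nu}{1+U\nu(\tau_u+\tau_x)+U\tau_u\tau_x\nu^2},\quad
#'       s_0 = \tau_s u_0 x_0 \nu.}
#'
#' @param rate presynaptic firing rate(s) (Hz, >= 0), vectorized.
#' @param params an [stp_params()] object.
#' @return list with components `s`, `u`, `x` (each the length of `rate`).
#' @export
stp_steady_state <- function(rate, params) {
  if (any(rate < 0)) stop("firing rate must be non-negative")
  U <- params$U; tu <- params$tau_u; tx <- params$tau_x
  D <- 1 + U * rate * (tu + tx) + U * tu * tx * rate^2
  u0 <- U * (1 + tu * rate) / (1 + U * tu * rate)
  x0 <- (1 + U * tu * rate) / D
  list(s = params$tau_s * u0 * x0 * rate, u = u0, x = x0)
}

# derivatives of the steady-state variables with respect to rate; used by the
# analytic manifold projection (chain rule through the bump profile)
stp_steady_state_deriv <- function(rate, params) {
  U <- params$U; tu <- params$tau_u; tx <- params$tau_x
  D <- 1 + U * rate * (tu + tx) + U * tu * tx * rate^2
  Dp <- U * (tu + tx) + 2 * U * tu * tx * rate
  du0 <- U * tu * (1 - U) / (1 + U * tu * rate)^2
  dx0 <- (U * tu * D - (1 + U * tu * rate) * Dp) / D^2
  dux <- U * (tu * D - (1 + tu * rate) * Dp) / D^2
  ux <- U * (1 + tu * rate) / D
  ds0 <- params$tau_s * (ux + rate * dux)
  list(ds = ds0, du = du0, dx = dx0, dux = dux, ux = ux)
}

#' Mean facilitation-depression product under Poisson firing
#'
#' Expected steady-state value of the combined release factor `u x` sampled at
#' the spike times of a Poisson train with rate `rate`, as used by the
#' firing-rate ("mean-field") reduction of the spike-based synapse:
#' \deqn{\langle u x\rangle = \frac{U(1+\nu\tau_u)}
#'   {U\nu(\tau_u+\tau_x+\nu\tau_u\tau_x)+1}.}
#' Equals `U` at zero rate.
#'
#' @inheritParams stp_steady_state
#' @return numeric vector of mean `u x` values.
#' @export
poisson_mean_ux <- function(rate, params) {
  if (any(rate < 0)) stop("firing rate must be non-negative")
  U <- params$U; tu <- params$tau_u; tx <- params$tau_x
  U * (rate * tu + 1) / (U * rate * (tu + tx + rate * tu * tx) + 1)
}

#' Spike-triggered update of the synaptic state
#'
#' Event update of the spike-based synapse. Using the values immediately
#' before the spike, the released fraction is `u * x`; then
#' `u <- u + U (1 - u)` and `x <- x - u x` (pre-spike `u`), and the release is
#' added to the synaptic activation `s`.
#'
#' @param state list with components `s`, `u`, `x` (pre-spike values).
#' @param params an [stp_params()] object.
#' @return list with components `state` (post-spike state) and `release`
#'   (the released fraction `u x`, which was added to `s`).
#' @export
stp_spike_update <- function(state, params) {
  u_pre <- state$u; x_pre <- state$x
  release <- u_pre * x_pre
  list(state = list(s = state$s + release,
                    u = u_pre + params$U * (1 - u_pre),
                    x = x_pre - x_pre * u_pre),
       release = release)
}

#' Exact decay of the synaptic state over a spike-free interval
#'
#' Closed-form relaxation of `(s, u, x)` towards the rest state
#' `(0, U, 1)` over an interval `dt` without presynaptic spikes.
#'
#' @param state list with components `s`, `u`, `x`.
#' @param dt interval length (s, >= 0).
#' @param params an [stp_params()] object.
#' @return decayed state list.
#' @export
stp_decay <- function(state, dt, params) {
  eu <- exp(-dt / params$tau_u)
  ex <- if (params$tau_x > 0) exp(-dt / params$tau_x) else 0
  list(s = state$s * exp(-dt / params$tau_s),
       u = params$U + (state$u - params$U) * eu,
       x = 1 + (state$x - 1) * ex)
}

#' Event-driven simulation of a single spike-based synapse
#'
#' Drives one facilitating/depressing synapse with an explicit spike train and
#' returns the pre-spike `u`, `x` and the released fraction at every spike.
#' Used as the Monte-Carlo oracle for [poisson_mean_ux()].
#'
#' @param spike_times increasing spike times (s).
#' @param params an [stp_params()] object.
#' @return data.frame with columns `t`, `u_pre`, `x_pre`, `release`.
#' @export
stp_simulate_spikes <- function(spike_times, params) {
  n <- length(spike_times)
  u <- params$U; x <- 1
  u_pre <- numeric(n); x_pre <- numeric(n)
  t_last <- 0
  eu_tab <- exp(-diff(c(0, spike_times)) / params$tau_u)
  ex_tab <- if (params$tau_x > 0) exp(-diff(c(0, spike_times)) / params$tau_x) else
    rep(0, n)
  for (k in seq_len(n)) {
    u <- params$U + (u - params$U) * eu_tab[k]
    x <- 1 + (x - 1) * ex_tab[k]
    u_pre[k] <- u; x_pre[k] <- x
    u <- u + params$U * (1 - u)
    x <- x - x_pre[k] * u_pre[k]
  }
  data.frame(t = spike_times, u_pre = u_pre, x_pre = x_pre,
             release = u_pre * x_pre)
}
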