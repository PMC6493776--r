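#' Periodic interpolant of a drift field
#'
#' Periodic cubic spline through the discretized drift field, exact at the
#' knots, with a continuous first derivative across the wrap point.
#'
#' @param field a [drift_field()] object (or a constant scalar).
#' @return function `A(phi)` accepting angles anywhere on the line (wrapped
#'   internally to `[-pi, pi)`).
#' @export
interpolate_field <- function(field) {
  if (is.numeric(field) && length(field) == 1L) {
    a <- field
    return(function(phi) rep(a, length(phi)))
  }
  stopifnot(inherits(field, "drift_field"), length(field$centers) >= 4L)
  if (!all(is.finite(field$A))) stop("drift field contains non-finite values")
  x0 <- field$centers[1L]
  per <- 2 * pi
  sp <- stats::splinefun(c(field$centers, field$centers[1L] + per),
                         c(field$A, field$A[1L]), method = "periodic")
  function(phi) sp(((phi - x0) %% per) + x0)
}

#' Wrap angles to the ring domain
#'
#' Maps angles to `[-pi, pi)` via `((phi + pi) mod 2pi) - pi`.
#'
#' @param phi angles (rad).
#' @return wrapped angles.
#' @export
wrap_angle <- function(phi) ((phi + pi) %% (2 * pi)) - pi

#' Integrate the bump-center Langevin equation
#'
#' Euler-Maruyama integration of
#' \eqn{\dot\varphi = A(\varphi) + \sqrt{B}\,\eta(t)} on the circle:
#' each step performs `phi <- phi + dt*A(phi) + sqrt(dt*B)*r` followed by the
#' wrap `((phi + pi) mod 2pi) - pi`.  All repetitions advance in lockstep
#' from a single seeded RNG stream, so an ensemble is reproducible given
#' `(seed, n_reps)`.
#'
#' @param B diffusion strength (rad^2/s, >= 0).
#' @param field a [drift_field()] object, a constant (rad/s), or a function
#'   of angle.
#' @param t_max duration (s).
#' @param dt time step (s); 0.1 s for retention-style runs, 0.01 s for the
#'   short distractor protocol.
#' @param phi0 initial angle(s) (rad); recycled to `n_reps`.
#' @param n_reps number of trajectories.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return object of class `trajectory_set`: list with `times` (length
#'   `n_t`) and `phi` (`n_reps x n_t` matrix, wrapped to `[-pi, pi)`).
#' @export
langevin_ensemble <- function(B, field = 0, t_max, dt = 0.1, phi0 = 0,
                              n_reps = 1L, seed = NULL) {
  stopifnot(B >= 0, dt > 0, t_max >= 0)
  A <- if (is.function(field)) field else interpolate_field(field)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling(t_max / dt - 1e-9)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  phi <- rep_len(wrap_angle(phi0), n_reps)
  out <- matrix(0, n_reps, n_steps + 1L)
  out[, 1L] <- phi
  sd_step <- sqrt(dt * B)
  for (m in seq_len(n_steps)) {
    phi <- phi + dt * A(phi) + sd_step * stats::rnorm(n_reps)
    phi <- wrap_angle(phi)
    out[, m + 1L] <- phi
  }
  structure(list(times = times, phi = out), class = "trajectory_set")
}

#' @rdname langevin_ensemble
#' @export
langevin_trajectory <- function(B, field = 0, t_max, dt = 0.1, phi0 = 0,
                                seed = NULL) {
  ens <- langevin_ensemble(B, field, t_max, dt, phi0, n_reps = 1L,
                           seed = seed)
  list(times = ens$times, phi = as.vector(ens$phi))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d repetitions x %d samples (t = 0..%.3g s)\n",
              nrow(x$phi), ncol(x$phi), max(x$times)))
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, max_reps = 20L, ...) {
  sel <- seq_len(min(nrow(x$phi), max_reps))
  graphics::matplot(x$times, t(x$phi[sel, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "center (rad)", ...)
  invisible(x)
}
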