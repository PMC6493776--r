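#' Ring geometry
#'
#' Uniform arrangement of `N` neurons on the ring, with angular positions
#' `theta_i = 2*pi*i/N - pi` for `i = 0, ..., N-1`.
#'
#' @param N number of neurons (integer >= 8).
#' @return object of class `ring_geometry` with fields `N` and `theta`.
#' @export
ring_geometry <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 8L)
  structure(list(N = N, theta = 2 * pi * (0:(N - 1)) / N - pi),
            class = "ring_geometry")
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Baseline weight of the normalized ring kernel
#'
#' Closed-form baseline `w0` such that the distance-dependent Gaussian weight
#' profile \eqn{w(\theta) = w_0 + (w_+ - w_0) e^{-\theta^2 / (2\sigma_w^2)}}
#' integrates to one over the ring: \eqn{(2\pi)^{-1}\oint w(\theta)d\theta = 1}.
#'
#' @param w_plus peak weight (>= 1).
#' @param kernel_width Gaussian width of the weight profile (rad, > 0).
#' @return baseline weight `w0` (negative for strong local excitation, giving
#'   effective lateral inhibition).
#' @export
kernel_w0 <- function(w_plus, kernel_width) {
  sw <- kernel_width
  g <- sqrt(2 / pi) * pi
  (w_plus * sw * erf(pi / (sqrt(2) * sw)) - g) /
    (sw * erf(pi / (sqrt(2) * sw)) - g)
}

#' Distance-dependent recurrent weight matrix
#'
#' Builds the circulant, symmetric excitatory-to-excitatory weight matrix
#' \eqn{w_{ij} = w(\theta_i - \theta_j)} with the Gaussian profile of
#' [kernel_w0()], normalized so every row averages to one (the discrete
#' analogue of the ring-integral normalization, which makes the total
#' recurrent drive invariant under changes of `w_plus` for uniform activity).
#'
#' @param geometry a [ring_geometry()] object (or integer N).
#' @param w_plus peak weight (>= 1).
#' @param kernel_width Gaussian width (rad, > 0).
#' @return `N x N` weight matrix with attributes `w0`, `w_plus`,
#'   `kernel_width`.
#' @export
ring_kernel <- function(geometry, w_plus, kernel_width) {
  if (!inherits(geometry, "ring_geometry")) geometry <- ring_geometry(geometry)
  stopifnot(w_plus >= 1, kernel_width > 0)
  th <- geometry$theta
  w0 <- kernel_w0(w_plus, kernel_width)
  d <- outer(th, th, function(a, b) {
    x <- abs(a - b)
    pmin(x, 2 * pi - x)
  })
  W <- w0 + (w_plus - w0) * exp(-d^2 / (2 * kernel_width^2))
  rm <- rowMeans(W)
  if (max(abs(rm - 1)) > 1e-3)
    stop(sprintf(paste0(
      "discrete kernel normalization failed (max |row mean - 1| = %.2e); ",
      "kernel_width is too small for N = %d"), max(abs(rm - 1)), geometry$N))
  # remove the residual O(h^2) discretization offset so row means are exact
  W <- W / rm[1L]
  attr(W, "w0") <- w0
  attr(W, "w_plus") <- w_plus
  attr(W, "kernel_width") <- kernel_width
  W
}

#' Generalized Gaussian bump profile
#'
#' Rate profile \eqn{\nu(\theta) = g_0 + g_1 \exp(-(|\theta|/g_\sigma)^{g_r})}
#' centered at zero, the parametrization used to describe (and to tune
#' networks towards) the stable bump shape.
#'
#' @param geometry a [ring_geometry()] object (or integer N), or a numeric
#'   vector of angles (rad).
#' @param g0 baseline rate (Hz, >= 0).
#' @param g1 peak rate above baseline (Hz, >= 0).
#' @param g_sigma half-width parameter (rad, > 0).
#' @param g_r sharpness exponent (> 0).
#' @return numeric vector of rates (Hz).
#' @export
generalized_gaussian_profile <- function(geometry, g0 = 0.1, g1 = 40,
                                         g_sigma = 0.5, g_r = 2.5) {
  stopifnot(g0 >= 0, g1 >= 0, g_sigma > 0, g_r > 0)
  th <- if (inherits(geometry, "ring_geometry")) geometry$theta
        else if (is.numeric(geometry) && length(geometry) > 1L) geometry
        else ring_geometry(geometry)$theta
  g0 + g1 * exp(-(abs(th) / g_sigma)^g_r)
}

# ---------------------------------------------------------------------------
# gain functions: stationary input -> rate mappings.  A gain object carries
# F(J) and its derivative; LIF-derived gains (see lif.R) additionally carry
# the leak-perturbation derivative.

#' Toy gain functions for abstract ring networks
#'
#' `gain_softplus()` is an analytic (infinitely differentiable) gain
#' \eqn{F(J) = r \log(1 + e^{(J - J_0)/\beta})}; with synaptic depression it
#' supports a stable bump even though it does not saturate.
#' `gain_threshold_quadratic()` is the saturating threshold-quadratic gain
#' \eqn{F(J) = r\, h^2/(1 + h^2)} with \eqn{h = \max(J - \theta_0, 0)}.
#'
#' @param r_max rate scale (Hz).
#' @param J0,beta softplus center and smoothness.
#' @param threshold threshold of the quadratic gain.
#' @return object of class `gain`: a list with functions `F(J)` and `dFdJ(J)`.
#' @export
gain_softplus <- function(r_max = 30, J0 = 0.6, beta = 0.25) {
  force(r_max); force(J0); force(beta)
  structure(list(
    F = function(J) {
      z <- (J - J0) / beta
      r_max * ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    },
    dFdJ = function(J) r_max / beta / (1 + exp(-(J - J0) / beta)),
    pars = c(r_max, J0, beta),
    label = "softplus"), class = "gain")
}

#' @rdname gain_softplus
#' @export
gain_threshold_quadratic <- function(r_max = 100, threshold = 0) {
  force(r_max); force(threshold)
  structure(list(
    F = function(J) {
      h <- pmax(J - threshold, 0)
      r_max * h^2 / (1 + h^2)
    },
    dFdJ = function(J) {
      h <- pmax(J - threshold, 0)
      r_max * 2 * h / (1 + h^2)^2
    },
    pars = c(r_max, threshold),
    label = "threshold_quadratic"), class = "gain")
}

# ---------------------------------------------------------------------------
# spatial derivatives along the family of shifted bump profiles

# derivative of a ring profile with respect to a positive shift of the bump
# center: moving the center by +delta maps the value at neuron i to the value
# formerly at i-1, hence d v_i / d phi = -(d/dtheta) v at fixed center.
ring_center_derivative <- function(v, method = c("spectral", "central")) {
  method <- match.arg(method)
  N <- length(v)
  if (method == "spectral") {
    k <- if (N %% 2L == 0L) c(0:(N / 2), -(N / 2 - 1):-1) else
      c(0:((N - 1) / 2), -((N - 1) / 2):-1)
    if (N %% 2L == 0L) k[N / 2 + 1] <- 0
    -Re(stats::fft(1i * k * stats::fft(v), inverse = TRUE)) / N
  } else {
    h <- 2 * pi / N
    idx <- function(k) ((seq_len(N) - 1 - k) %% N) + 1
    (v[idx(1)] - v[idx(-1)]) / (2 * h)
  }
}

#' Solve for the stationary bump state
#'
#' Finds the self-consistent fixed point
#' \eqn{\phi_i = F\big(N^{-1}\sum_j w_{ij}\, s_0(\phi_j)\big)}
#' of the rate network with steady-state synapses, by damped fixed-point
#' iteration, and assembles the quantities the manifold theory consumes: the
#' rate profile `phi0`, inputs `J0`, their derivative under center shifts
#' `dJ0_dphi`, and the gain slope `phi0_prime`.
#'
#' @param weights weight matrix from [ring_kernel()].
#' @param gain a `gain` object ([gain_softplus()], [gain_threshold_quadratic()]
#'   or an LIF gain from [lif_gain()]).
#' @param stp an [stp_params()] object.
#' @param init initial rate profile (Hz); defaults to a Gaussian bump at
#'   center 0. Must be strictly positive somewhere.
#' @param center desired center angle (rad); the converged profile is rotated
#'   so its rate peak sits on the grid point nearest `center`.
#' @param tol fixed-point tolerance on max rate change (Hz).
#' @param max_iter iteration limit.
#' @param damping damping factor in (0, 1]; the update is
#'   `phi <- (1-damping)*phi + damping*F(J(phi))`.
#' @param deriv_method `"spectral"` (default) or `"central"` differences for
#'   `dJ0_dphi`.
#' @return object of class `bump_state`: list with `phi0`, `J0`, `dJ0_dphi`,
#'   `phi0_prime`, `center`, `N`, `residual`, plus steady synapse vectors
#'   `s0`, `u0`, `x0` and the `stp`/`gain` used.
#' @export
solve_bump <- function(weights, gain, stp, init = NULL, center = 0,
                       tol = 1e-9, max_iter = 20000L, damping = 0.5,
                       method = c("iterate", "newton"),
                       deriv_method = c("spectral", "central")) {
  deriv_method <- match.arg(deriv_method)
  method <- match.arg(method)
  N <- nrow(weights)
  geom <- ring_geometry(N)
  if (is.null(init)) init <- 40 * exp(-geom$theta^2 / (2 * 0.3^2)) + 0.1
  if (!any(init > 0)) stop("initial profile must be positive somewhere")
  phi <- init
  Wn <- weights / N
  res <- Inf
  # gains whose rate depends on the rate itself (mean-voltage correction)
  # accept the current rate as a second argument; the solver then finds the
  # joint fixed point of both relations
  takes_phi <- length(formals(gain$F)) >= 2L
  Fev <- if (takes_phi) function(J, phi) gain$F(J, phi) else
    function(J, phi) gain$F(J)
  if (method == "iterate") {
    for (it in seq_len(max_iter)) {
      J <- as.vector(Wn %*% stp_steady_state(phi, stp)$s)
      phin <- Fev(J, phi)
      res <- max(abs(phin - phi))
      if (!all(is.finite(phin)))
        stop(sprintf("bump iteration diverged at step %d", it))
      phi <- (1 - damping) * phi + damping * phin
      if (res < tol) break
    }
  } else {
    # Newton on R(phi) = phi - F(J(phi)); the fixed point can be an
    # amplitude-saddle of the forward map when the inhibitory rate is frozen
    # into the gain, so forward iteration may collapse where Newton converges
    for (it in seq_len(100L)) {
      J <- as.vector(Wn %*% stp_steady_state(phi, stp)$s)
      Fv <- Fev(J, phi)
      R <- phi - Fv
      res <- max(abs(R))
      if (res < tol) break
      ds <- stp_steady_state_deriv(phi, stp)$ds
      dF <- if (takes_phi) gain$dFdJ(J, phi) else gain$dFdJ(J)
      Jac <- diag(N) - (dF * Wn) %*% diag(ds)
      step <- tryCatch(solve(Jac, R), error = function(e)
        stop("no bump: singular Newton system"))
      lam <- 1
      repeat {
        phin <- pmax(phi - lam * step, 0)
        Jn <- as.vector(Wn %*% stp_steady_state(phin, stp)$s)
        rn <- max(abs(phin - Fev(Jn, phin)))
        if (rn < res || lam < 1e-3) break
        lam <- lam / 2
      }
      phi <- phin
    }
  }
  if (res >= tol)
    stop(sprintf("no bump: fixed point not reached (last residual %.3e Hz)",
                 res))
  if (max(phi) - min(phi) < 1e-3 * max(phi))
    stop(sprintf(paste0("no bump: iteration collapsed to a uniform state ",
                        "(rate %.3g Hz, residual %.3e)"), max(phi), res))
  # rotate so the peak sits at the grid point nearest `center`
  k_target <- which.min(abs(atan2(sin(geom$theta - center),
                                  cos(geom$theta - center))))
  k_peak <- which.max(phi)
  rot <- function(v, k) v[((seq_along(v) - 1 - k) %% N) + 1]
  phi <- rot(phi, k_target - k_peak)
  J <- as.vector(Wn %*% stp_steady_state(phi, stp)$s)
  phi0 <- Fev(J, phi)
  ss <- stp_steady_state(phi0, stp)
  out <- list(
    phi0 = phi0,
    J0 = J,
    dJ0_dphi = ring_center_derivative(J, deriv_method),
    phi0_prime = if (takes_phi) gain$dFdJ(J, phi0) else gain$dFdJ(J),
    center = geom$theta[k_target],
    N = N,
    residual = max(abs(phi0 - phi)),
    s0 = ss$s, u0 = ss$u, x0 = ss$x,
    stp = stp, gain = gain, weights = weights,
    deriv_method = deriv_method,
    theta = geom$theta)
  class(out) <- "bump_state"
  out
}

#' @export
print.bump_state <- function(x, ...) {
  cat(sprintf(
    paste0("Bump state on N = %d ring: peak %.2f Hz, baseline %.3g Hz,\n",
           "  center %.3f rad, solver residual %.2e Hz\n"),
    x$N, max(x$phi0), min(x$phi0), x$center, x$residual))
  invisible(x)
}

#' @export
plot.bump_state <- function(x, ...) {
  graphics::plot(x$theta, x$phi0, type = "l", xlab = "position (rad)",
                 ylab = "rate (Hz)", main = "stationary bump profile", ...)
  invisible(x)
}

#' Rotate a bump state along the ring
#'
#' Index-shifts every per-neuron vector of a bump state by `k` grid steps
#' (positive `k` moves the center by `+2*pi*k/N`); by ring symmetry the
#' result is an equally valid stationary state.
#'
#' @param bump a [solve_bump()] result.
#' @param k integer number of grid steps.
#' @return rotated `bump_state`.
#' @export
rotate_bump <- function(bump, k) {
  N <- bump$N
  rot <- function(v) v[((seq_len(N) - 1 - k) %% N) + 1]
  out <- bump
  for (f in c("phi0", "J0", "dJ0_dphi", "phi0_prime", "s0", "u0", "x0"))
    out[[f]] <- rot(bump[[f]])
  out$center <- atan2(sin(bump$center + 2 * pi * k / N),
                      cos(bump$center + 2 * pi * k / N))
  out
}

#' Assemble a bump state from a measured rate profile
#'
#' Builds the coefficient bundle the manifold theory consumes from a rate
#' profile measured in simulation (or constructed otherwise): steady inputs
#' from the weights and steady synapses, gain slopes from the supplied gain,
#' and the spatial derivative of the input.  The profile is first rotated so
#' its peak sits at angle 0.  No self-consistency is imposed: the profile is
#' taken as the operating point, exactly as when feeding rates measured from
#' a spiking network into the theory.
#'
#' @param phi0 per-neuron rates (Hz).
#' @param weights ring weight matrix (same size).
#' @param gain a `gain` object.
#' @param stp an [stp_params()] object.
#' @param deriv_method spatial derivative method.
#' @return object of class `bump_state`.
#' @export
bump_from_profile <- function(phi0, weights, gain, stp,
                              deriv_method = c("spectral", "central")) {
  deriv_method <- match.arg(deriv_method)
  N <- length(phi0)
  stopifnot(nrow(weights) == N)
  geom <- ring_geometry(N)
  k_target <- which.min(abs(geom$theta))
  k_peak <- which.max(phi0)
  rot <- function(v, k) v[((seq_along(v) - 1 - k) %% N) + 1]
  phi0 <- rot(phi0, k_target - k_peak)
  ss <- stp_steady_state(phi0, stp)
  J <- as.vector(weights %*% ss$s) / N
  takes_phi <- length(formals(gain$F)) >= 2L
  out <- list(
    phi0 = phi0, J0 = J,
    dJ0_dphi = ring_center_derivative(J, deriv_method),
    phi0_prime = if (takes_phi) gain$dFdJ(J, phi0) else gain$dFdJ(J),
    center = geom$theta[k_target], N = N,
    residual = NA_real_,
    s0 = ss$s, u0 = ss$u, x0 = ss$x,
    stp = stp, gain = gain, weights = weights,
    deriv_method = deriv_method, theta = geom$theta)
  class(out) <- "bump_state"
  out
}
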