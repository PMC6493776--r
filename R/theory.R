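#' Linearized synaptic dynamics around the bump
#'
#' Assembles the `3N x 3N` Jacobian of the coupled `(s, u, x)` dynamics at the
#' stationary bump, in block order (s, u, x). Under the separation of time
#' scales between neuronal and synaptic dynamics the rate deviation of neuron
#' i is slaved to its input, `dphi_i = phi0'_i (W ds)_i / N`, which couples the
#' s-block back into all three equations. For a valid ring attractor the
#' matrix has a (numerically) zero eigenvalue whose eigenvector is the
#' translation mode of the bump.
#'
#' @param bump a [solve_bump()] result.
#' @param stp an [stp_params()] object; defaults to the one stored in `bump`.
#' @param weights weight matrix; defaults to the one stored in `bump`.
#' @return object of class `linearized_system`: list with the matrix `K`,
#'   the block size `N`, and the right null vector `e_r`.
#' @export
build_K <- function(bump, stp = bump$stp, weights = bump$weights) {
  N <- bump$N
  if (nrow(weights) != N) stop("weight matrix does not match bump size")
  if (stp$tau_x <= 0)
    stop("build_K requires tau_x > 0 (with tau_x = 0 the x-block is absent); ",
         "use a small positive tau_x or the closed-form coefficients")
  Wn <- weights / N
  u0 <- bump$u0; x0 <- bump$x0; phi0 <- bump$phi0; fp <- bump$phi0_prime
  D <- function(v) diag(v, N, N)
  Z <- matrix(0, N, N)
  K <- rbind(
    cbind(-diag(N) / stp$tau_s + D(u0 * x0 * fp) %*% Wn,
          D(phi0 * x0), D(phi0 * u0)),
    cbind(stp$U * D((1 - u0) * fp) %*% Wn,
          -diag(N) / stp$tau_u - stp$U * D(phi0), Z),
    cbind(-D(u0 * x0 * fp) %*% Wn,
          -D(x0 * phi0), -diag(N) / stp$tau_x - D(u0 * phi0)))
  structure(list(K = K, N = N, e_r = right_null_vector(bump, stp),
                 bump = bump),
            class = "linearized_system")
}

#' Translation (right null) vector of the linearized system
#'
#' The derivative of the steady synaptic state along the attractor manifold,
#' `e_r = d y0 / d phi = (ds0/dphi, du0/dphi, dx0/dphi)`, computed by the
#' chain rule through the rate profile: `d s0_i/d phi = s0'(phi0_i) *
#' phi0'_i * dJ0_i/dphi`, etc.
#'
#' @inheritParams build_K
#' @return numeric vector of length `3N`.
#' @export
right_null_vector <- function(bump, stp = bump$stp) {
  if (max(bump$phi0) - min(bump$phi0) < 1e-9 * max(abs(bump$phi0)))
    stop("degenerate (flat) rate profile: translation mode undefined")
  d <- stp_steady_state_deriv(bump$phi0, stp)
  dphi <- bump$phi0_prime * bump$dJ0_dphi
  c(d$ds * dphi, d$du * dphi, d$dx * dphi)
}

# pointwise u- and x-components of the (unnormalized) left null vector,
# relative to its s-component dJ0/dphi; obtained by solving the u- and x-rows
# of K^T y' = 0, which are diagonal
left_null_factors <- function(phi0, stp) {
  U <- stp$U; tu <- stp$tau_u; tx <- stp$tau_x
  ss <- stp_steady_state(phi0, stp)
  zf <- ss$u * phi0 * tx / (1 + tx * ss$u * phi0)
  vf <- tu * ss$x * phi0 / ((1 + U * tu * phi0) * (1 + tx * ss$u * phi0))
  list(v = vf, z = zf, u0 = ss$u, x0 = ss$x)
}

#' Analytical prefactors C_i and normalization S
#'
#' Closed-form coefficients of the manifold projection. The per-neuron
#' prefactor
#' \deqn{C_i = \frac{U(1 + 2\tau_u\phi_{0,i} + U\tau_u^2\phi_{0,i}^2)}
#'   {(1 + U\phi_{0,i}(\tau_u + \tau_x) + U\tau_u\tau_x\phi_{0,i}^2)^2}}
#' weighs the firing of neuron i in the diffusion and drift sums; the scalar
#' `S` normalizes the left null vector so that `e_l . e_r = 1`,
#' \eqn{S = \sum_i (dJ_{0,i}/d\varphi)^2\, \phi_{0,i}'\,
#'   [\tau_s (u_0 x_0 + \phi_0\, d(u_0x_0)/d\nu) + v_i\, du_0/d\nu +
#'    z_i\, dx_0/d\nu]_i,}
#' where `v_i`, `z_i` are the pointwise u/x loadings of the left null vector.
#' In the static-synapse limit (`U = 1`, `tau_u -> 0`, `tau_x = 0`) this
#' reduces to `C_i = 1` and `S = tau_s * sum((dJ0/dphi)^2 * phi0')`.
#'
#' @inheritParams build_K
#' @return list with vector `C` and scalar `S`.
#' @export
prefactors <- function(bump, stp = bump$stp) {
  U <- stp$U; tu <- stp$tau_u; tx <- stp$tau_x
  phi0 <- bump$phi0
  denom <- 1 + U * phi0 * (tu + tx) + U * tu * tx * phi0^2
  C <- U * (1 + 2 * tu * phi0 + U * tu^2 * phi0^2) / denom^2
  lf <- left_null_factors(phi0, stp)
  d <- stp_steady_state_deriv(phi0, stp)
  S <- sum(bump$dJ0_dphi^2 * bump$phi0_prime *
             (stp$tau_s * (lf$u0 * lf$x0 + phi0 * d$dux) +
                lf$v * d$du + lf$z * d$dx))
  list(C = C, S = S)
}

#' Theory coefficients of the reduced bump dynamics
#'
#' Computes all closed-form coefficients of the one-dimensional Langevin
#' reduction at once: prefactors `C_i`, normalization `S`, diffusion strength
#' \deqn{B = \sum_i (C_i/S)^2 (dJ_{0,i}/d\varphi)^2\, \phi_{0,i}}
#' (units rad^2/s, with degree and index conversions), and the per-neuron
#' drift weights \eqn{(C_i/S)\, dJ_{0,i}/d\varphi} (units s) that map rate
#' perturbations to center velocity.
#'
#' @inheritParams build_K
#' @return object of class `attractor_theory`: list with `C`, `S`, `B`
#'   (rad^2/s), `B_deg2` (deg^2/s), `B_idx2` (neuron-index^2/s),
#'   `drift_weights`, `N`, `stp` and the generating `bump`.
#' @export
attractor_theory <- function(bump, stp = bump$stp) {
  pf <- prefactors(bump, stp)
  if (pf$S <= 0)
    stop(sprintf(paste0("normalization S = %.3g <= 0: the depression time ",
                        "constant exceeds its critical value; the projection ",
                        "breaks down"), pf$S))
  dw <- (pf$C / pf$S) * bump$dJ0_dphi
  B <- sum(dw^2 * bump$phi0)
  structure(list(
    C = pf$C, S = pf$S, B = B,
    B_deg2 = B * (180 / pi)^2,
    B_idx2 = B * (bump$N / (2 * pi))^2,
    drift_weights = dw, N = bump$N, stp = stp, bump = bump),
    class = "attractor_theory")
}

#' @export
print.attractor_theory <- function(x, ...) {
  cat(sprintf(
    paste0("Ring-attractor projection (N = %d):\n",
           "  S = %.4g, B = %.4g rad^2/s (%.4g deg^2/s, %.4g idx^2/s)\n",
           "  STP: U = %g, tau_u = %g ms, tau_x = %g ms, tau_s = %g ms\n"),
    x$N, x$S, x$B, x$B_deg2, x$B_idx2,
    x$stp$U, 1000 * x$stp$tau_u, 1000 * x$stp$tau_x, 1000 * x$stp$tau_s))
  invisible(x)
}

#' Diffusion strength of the bump center
#'
#' Convenience wrapper returning only the diffusion strength `B` from
#' [attractor_theory()].
#'
#' @inheritParams build_K
#' @param units one of `"rad2"` (rad^2/s), `"deg2"` (deg^2/s), `"idx2"`
#'   (neuron index^2/s).
#' @return diffusion strength in the requested units.
#' @export
diffusion_B <- function(bump, stp = bump$stp,
                        units = c("rad2", "deg2", "idx2")) {
  units <- match.arg(units)
  th <- attractor_theory(bump, stp)
  switch(units, rad2 = th$B, deg2 = th$B_deg2, idx2 = th$B_idx2)
}

#' Numeric null-vector projection (independent oracle)
#'
#' Computes the left null vector of the assembled Jacobian `K` numerically
#' (singular vector of the smallest singular value), normalizes it against
#' the translation mode (`e_l . e_r = 1`), and evaluates the diffusion
#' strength and drift weights directly from the noise loadings
#' \eqn{(e_l^{(s)} u_0 x_0 + e_l^{(u)} U(1-u_0) - e_l^{(x)} u_0 x_0)_i},
#' without using any closed-form coefficient. Serves as the independent
#' cross-check of [attractor_theory()].
#'
#' @param lin a [build_K()] result (or a `bump_state`, in which case `K` is
#'   built first).
#' @param stp an [stp_params()] object.
#' @return list with `B`, `drift_weights`, `e_l`, `S` (scalar recovered from
#'   the proportionality of the s-block to `dJ0/dphi`), and the singular
#'   values `sv_min`, `sv_next`.
#' @export
numeric_null_projection <- function(lin, stp = NULL) {
  if (inherits(lin, "bump_state")) {
    bump <- lin
    if (is.null(stp)) stp <- bump$stp
    lin <- build_K(bump, stp)
  } else {
    bump <- lin$bump
    if (is.null(stp)) stp <- bump$stp
  }
  K <- lin$K; N <- lin$N
  sv <- svd(t(K))
  n3 <- 3L * N
  if (sv$d[n3 - 1L] < 10 * sv$d[n3])
    stop(sprintf(paste0("ambiguous null space: smallest singular values ",
                        "%.3e and %.3e are not separated"),
                 sv$d[n3], sv$d[n3 - 1L]))
  e_l <- sv$v[, n3]
  e_l <- e_l / sum(e_l * lin$e_r)
  els <- e_l[1:N]; elu <- e_l[N + 1:N]; elx <- e_l[2 * N + 1:N]
  phi0 <- bump$phi0
  ss <- stp_steady_state(phi0, stp)
  ss_u <- ss$u; ss_x <- ss$x
  load <- els * ss_u * ss_x + elu * stp$U * (1 - ss_u) - elx * ss_u * ss_x
  B <- sum(load^2 * phi0)
  dJ <- if (!is.null(bump)) bump$dJ0_dphi else NULL
  S <- if (!is.null(dJ)) {
    idx <- which(abs(dJ) > 1e-6 * max(abs(dJ)))
    stats::median(dJ[idx] / els[idx])
  } else NA_real_
  list(B = B, drift_weights = load, e_l = e_l, S = S,
       sv_min = sv$d[n3], sv_next = sv$d[n3 - 1L])
}

#' Drift field induced by given rate perturbations
#'
#' Maps per-neuron firing-rate deviations from the bump profile to the
#' deterministic center velocity at every realizable center position:
#' \deqn{A(\varphi_k) = \sum_i \frac{C_i}{S}\frac{dJ_{0,i}}{d\varphi}\,
#'   \Delta\phi_i(\varphi_k).}
#'
#' @param theory an [attractor_theory()] object.
#' @param delta_phi either a numeric vector (length N, the same deviation
#'   pattern in bump-centered coordinates for every center) or an `N x N`
#'   matrix whose column k holds the deviations `Delta phi_i(phi_k)` for the
#'   bump centered at `phi_k = 2*pi*(k-1)/N - pi`.
#' @return object of class `drift_field`: list with `centers` (rad) and `A`
#'   (rad/s).
#' @export
drift_field_from_perturbation <- function(theory, delta_phi) {
  N <- theory$N
  dw <- theory$drift_weights
  if (is.matrix(delta_phi)) {
    stopifnot(nrow(delta_phi) == N)
    A <- as.vector(crossprod(delta_phi, dw))
  } else {
    stopifnot(length(delta_phi) == N)
    A <- rep(sum(dw * delta_phi), N)
  }
  # column k holds the perturbation for the bump shifted k grid steps from
  # its stored center
  c0 <- if (!is.null(theory$bump)) theory$bump$center else -pi
  centers <- wrap_angle(c0 + 2 * pi * (0:(N - 1)) / N)
  ord <- order(centers)
  drift_field(centers[ord], A[ord])
}

#' Construct a drift field object
#'
#' @param centers center angles (rad), uniformly spaced on `[-pi, pi)`.
#' @param A drift velocities at the centers (rad/s).
#' @return object of class `drift_field`.
#' @export
drift_field <- function(centers, A) {
  stopifnot(length(centers) == length(A), all(is.finite(A)))
  structure(list(centers = centers, A = A), class = "drift_field")
}

#' @export
print.drift_field <- function(x, ...) {
  cat(sprintf("Drift field on %d centers: RMS %.4g rad/s, range [%.4g, %.4g]\n",
              length(x$centers), sqrt(mean(x$A^2)), min(x$A), max(x$A)))
  invisible(x)
}

#' @export
plot.drift_field <- function(x, ...) {
  graphics::plot(x$centers, x$A, type = "l", xlab = "center (rad)",
                 ylab = "A (rad/s)", main = "drift field", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Critical depression time constant
#'
#' Finds the smallest depression time constant `tau_x,c` at which the
#' normalization `S` crosses zero for a fixed bump shape (rates, inputs and
#' gain slopes held at the supplied bump), by bracketing and bisection.
#' Beyond this point the projection breaks down and predicted diffusion and
#' drift diverge.
#'
#' @param bump a [solve_bump()] result (its shape is held fixed).
#' @param stp an [stp_params()] object supplying `U`, `tau_u`, `tau_s`;
#'   `tau_x` is the free variable.
#' @param tau_x_max upper end of the search interval (s).
#' @param tol absolute tolerance on the root (s).
#' @return critical `tau_x` in seconds.
#' @export
critical_tau_x <- function(bump, stp = bump$stp, tau_x_max = 2,
                           tol = 1e-7) {
  Sof <- function(tx) {
    p <- stp_params(stp$U, stp$tau_u, tx, stp$tau_s)
    prefactors(bump, p)$S
  }
  lo <- 1e-6
  if (Sof(lo) <= 0) stop("S is already non-positive at tau_x ~ 0")
  hi <- tau_x_max
  if (Sof(hi) > 0)
    stop(sprintf("no critical point: S(tau_x = %g s) is still positive", hi))
  stats::uniroot(Sof, c(lo, hi), tol = tol)$root
}

#' System-size scaling of the theory coefficients
#'
#' Rescales coefficients computed at a reference discretization `N_ref` to a
#' target network size `N`: the normalization scales as `S ~ N`, hence the
#' diffusion strength as `B(N) = (N_ref/N) B*`; the connectivity-induced
#' squared drift field scales as `(N_ref/N)^2` and the leak-heterogeneity
#' term as `N_ref/N`.
#'
#' @param B diffusion strength at the reference size (rad^2/s).
#' @param sq_field_connectivity connectivity term of the expected squared
#'   field at the reference size (rad^2/s^2).
#' @param sq_field_leak leak term at the reference size (rad^2/s^2).
#' @param N_ref reference size.
#' @param N target size.
#' @return list with rescaled `B`, `sq_field_connectivity`, `sq_field_leak`,
#'   and their sum `sq_field`.
#' @export
scale_with_N <- function(B, sq_field_connectivity = 0, sq_field_leak = 0,
                         N_ref, N) {
  r <- N_ref / N
  list(B = B * r,
       sq_field_connectivity = sq_field_connectivity * r^2,
       sq_field_leak = sq_field_leak * r,
       sq_field = sq_field_connectivity * r^2 + sq_field_leak * r)
}
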