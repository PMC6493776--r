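#' Conductance-based LIF network parameters
#'
#' Physiological constants of the two-population (excitatory/inhibitory)
#' conductance-based leaky integrate-and-fire network, in the standard
#' visuospatial working-memory parametrization (pyramidal/interneuron
#' constants and external AMPA drive of the Compte et al. 2000 /
#' Brunel & Wang 2001 model family). Recurrent conductance scales
#' (`g_EE`, `g_EI`, `g_IE`, `g_II`) and the kernel width are free parameters
#' set by [tune_network()]; the values stored here are the tuned
#' scale-invariant conductances `g_tilde = g * N_pre` (nS), so that
#' simulations at any size use `g = g_tilde / N_pre`.
#'
#' Units: capacitance nF, conductance nS, potential mV, time s.
#'
#' @param N_E,N_I excitatory / inhibitory population sizes.
#' @param Cm_E,Cm_I membrane capacitances (nF).
#' @param gL_E,gL_I leak conductances (nS).
#' @param V_L,V_E,V_I,V_thr,V_res leak, excitatory and inhibitory reversal,
#'   threshold and reset potentials (mV).
#' @param tau_ref_E,tau_ref_I refractory periods (s).
#' @param tau_ext,tau_E,tau_I synaptic decay times (s) of external AMPA,
#'   recurrent (NMDA-like) excitation, and GABA inhibition.
#' @param N_ext,nu_ext number and rate (Hz) of external Poisson inputs per
#'   neuron.
#' @param g_ext_E,g_ext_I external AMPA conductances (nS).
#' @param g_EE,g_EI,g_IE,g_II scale-invariant recurrent conductances
#'   `g_tilde` (nS); `NA` until tuned.
#' @param w_plus,kernel_width peak weight and width (rad) of the recurrent
#'   excitatory kernel.
#' @return object of class `lif_params`.
#' @export
lif_params <- function(N_E = 800L, N_I = 200L,
                       Cm_E = 0.5, Cm_I = 0.2,
                       gL_E = 25, gL_I = 20,
                       V_L = -70, V_E = 0, V_I = -70,
                       V_thr = -50, V_res = -60,
                       tau_ref_E = 0.002, tau_ref_I = 0.001,
                       tau_ext = 0.002, tau_E = 0.1, tau_I = 0.01,
                       N_ext = 1000L, nu_ext = 1.8,
                       g_ext_E = 3.1, g_ext_I = 2.38,
                       g_EE = NA, g_EI = NA, g_IE = NA, g_II = NA,
                       w_plus = 4, kernel_width = 0.35) {
  stopifnot(V_res < V_thr)
  structure(list(
    N_E = as.integer(N_E), N_I = as.integer(N_I),
    Cm_E = Cm_E, Cm_I = Cm_I, gL_E = gL_E, gL_I = gL_I,
    V_L = V_L, V_E = V_E, V_I = V_I, V_thr = V_thr, V_res = V_res,
    tau_ref_E = tau_ref_E, tau_ref_I = tau_ref_I,
    tau_ext = tau_ext, tau_E = tau_E, tau_I = tau_I,
    N_ext = as.integer(N_ext), nu_ext = nu_ext,
    g_ext_E = g_ext_E, g_ext_I = g_ext_I,
    g_EE = g_EE, g_EI = g_EI, g_IE = g_IE, g_II = g_II,
    w_plus = w_plus, kernel_width = kernel_width), class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("Conductance LIF network: N_E = %d, N_I = %d\n", x$N_E, x$N_I))
  cat(sprintf("  tuned conductances (g_tilde, nS): g_EE = %.4g, g_EI = %.4g, g_IE = %.4g, g_II = %.4g\n",
              x$g_EE, x$g_EI, x$g_IE, x$g_II))
  cat(sprintf("  kernel: w_plus = %g, width = %.4g rad\n",
              x$w_plus, x$kernel_width))
  invisible(x)
}

# composite dimensionless scales of the rate reduction for one population.
# g_EE etc. are stored as scale-invariant g_tilde = g * N_pre, so
# T_E = N_E g_E / gL = g_tilde_E / gL independently of N.
lif_composites <- function(par, pop = c("E", "I")) {
  pop <- match.arg(pop)
  if (pop == "E") {
    gL <- par$gL_E; Cm <- par$Cm_E
    T_E <- par$g_EE / gL
    T_I <- par$tau_I * par$g_EI / gL   # g_tilde_EI = g_EI * N_I
    g_ext <- par$g_ext_E; tau_ref <- par$tau_ref_E
  } else {
    gL <- par$gL_I; Cm <- par$Cm_I
    T_E <- par$g_IE / gL
    T_I <- par$tau_I * par$g_II / gL
    g_ext <- par$g_ext_I; tau_ref <- par$tau_ref_I
  }
  list(gL = gL, Cm = Cm, T_E = T_E, T_I = T_I,
       T_ext = par$N_ext * par$tau_ext * g_ext / gL,
       g_ext = g_ext, tau_ref = tau_ref)
}

# scaled complementary error function, stable for large arguments
# (pracma::erfcx overflows near x = 27; switch to the asymptotic series)
erfcx_safe <- function(x) {
  out <- x * 0
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    z <- x[big]
    iz2 <- 1 / (2 * z^2)
    out[big] <- (1 - iz2 + 3 * iz2^2 - 15 * iz2^3) / (z * sqrt(pi))
  }
  out
}

# Gauss-Legendre nodes for the Siegert integral, cached
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n = 96L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

# integral of X(u) = exp(u^2)(1 + erf(u)) = erfcx(-u) over [beta, alpha],
# vectorized over (alpha, beta); alpha is capped (the rate underflows anyway)
siegert_integral <- function(alpha, beta, n = 96L) {
  alpha <- pmin(alpha, 26)
  g <- gl_nodes(n)
  mid <- (alpha + beta) / 2
  hw <- (alpha - beta) / 2
  u <- outer(g$x, hw) + rep(mid, each = n)    # n x m nodes
  vals <- erfcx_safe(-u)
  hw * as.vector(crossprod(g$w, vals))
}

# core rate evaluation; all inputs vectorized over J (phi likewise).
# Returns rate plus every intermediate needed for analytic derivatives.
lif_rate_components <- function(J, nu_I, par, pop = "E", phi,
                                delta_L = 0) {
  cp <- lif_composites(par, pop)
  S <- 1 + cp$T_I * nu_I + cp$T_ext * par$nu_ext + cp$T_E * J
  mu <- ((par$V_I - par$V_L) * cp$T_I * nu_I +
           (par$V_E - par$V_L) * (cp$T_ext * par$nu_ext + cp$T_E * J)) / S +
    delta_L / S
  tau <- cp$Cm / (cp$gL * S)
  Vbar <- mu + par$V_L - (par$V_thr - par$V_res) * phi * tau
  sig <- (cp$g_ext / cp$Cm) * (par$V_E - Vbar) * par$tau_ext *
    sqrt(par$N_ext * par$nu_ext * tau)
  r <- par$tau_ext / tau
  qa <- (par$V_thr - par$V_L - mu) / sig
  alpha <- qa * (1 + r / 2) + 1.03 * sqrt(r) - r / 2
  beta <- (par$V_res - par$V_L - mu) / sig
  I <- siegert_integral(alpha, beta)
  Fr <- 1 / (cp$tau_ref + sqrt(pi) * tau * I)
  list(F = Fr, S = S, mu = mu, tau = tau, sigma = sig, Vbar = Vbar,
       alpha = alpha, beta = beta, I = I, r = r, qa = qa, cp = cp)
}

#' Firing rate of the conductance LIF neuron (diffusion approximation)
#'
#' Mean first-passage-time rate of the conductance-based LIF neuron under
#' Poisson input, including the fast-synapse (AMPA-filtered) correction to
#' the threshold bound and the mean-voltage correction to the input
#' fluctuation.  The fluctuation scale depends on the mean voltage, which
#' depends on the rate itself; if `phi` (the rate entering the mean-voltage
#' correction) is not supplied it is found by damped fixed-point iteration.
#'
#' @param J dimensionless recurrent excitatory input (vectorized). For the
#'   excitatory population this is the normalized steady synaptic activation
#'   `(1/N_E) sum_j w_ij tau_E <u x>_j phi_j`; for the inhibitory population
#'   use `tau_E * mean(phi_E)`.
#' @param nu_I inhibitory population rate (Hz).
#' @param par an [lif_params()] object.
#' @param pop `"E"` or `"I"`.
#' @param phi rate used in the mean-voltage correction (Hz); if `NULL`,
#'   solved self-consistently.
#' @param delta_L leak reversal-potential offset (mV), entering the membrane
#'   operating point as `delta_L / S`.
#' @param max_iter,tol iteration controls for the self-consistency loop.
#' @return numeric vector of rates (Hz).
#' @export
siegert_rate <- function(J, nu_I, par, pop = "E", phi = NULL, delta_L = 0,
                         max_iter = 200L, tol = 1e-10) {
  if (any(J < -1e-12) || nu_I < 0) stop("J and nu_I must be non-negative")
  if (!is.null(phi))
    return(lif_rate_components(J, nu_I, par, pop, phi, delta_L)$F)
  phi <- rep(1, length(J))
  for (it in seq_len(max_iter)) {
    Fr <- lif_rate_components(J, nu_I, par, pop, phi, delta_L)$F
    if (max(abs(Fr - phi)) < tol) return(Fr)
    phi <- 0.5 * phi + 0.5 * Fr
  }
  stop(sprintf("siegert_rate: self-consistency not reached (residual %.3e Hz)",
               max(abs(Fr - phi))))
}

# shared derivative core: assembles dF for a perturbation with given
# dmu/dtheta and dtau/dtheta (all three alpha/beta pathways included)
lif_rate_derivative <- function(comp, par, dmu, dtau) {
  with(comp, {
    dsig_dV <- -sigma / (par$V_E - Vbar)
    dsig_dtau <- sigma / (2 * tau)
    # Vbar = mu + V_L - (Vthr-Vres) phi tau, phi held at the evaluated rate
    phi_held <- F
    dVbar <- dmu - (par$V_thr - par$V_res) * phi_held * dtau
    dsig <- dsig_dV * dVbar + dsig_dtau * dtau
    da_dmu <- -(1 + r / 2) / sigma
    da_dsig <- -qa * (1 + r / 2) / sigma
    dr <- -r / tau * dtau
    da_dr_term <- (qa / 2 + 1.03 / (2 * sqrt(r)) - 0.5) * dr
    dalpha <- da_dmu * dmu + da_dsig * dsig + da_dr_term
    db_dmu <- -1 / sigma
    db_dsig <- -beta / sigma
    dbeta <- db_dmu * dmu + db_dsig * dsig
    Xa <- erfcx_safe(-pmin(alpha, 26))
    Xb <- erfcx_safe(-beta)
    dI <- Xa * dalpha - Xb * dbeta
    -F^2 * sqrt(pi) * (dtau * I + tau * dI)
  })
}

#' Derivative of the LIF rate with respect to the recurrent input
#'
#' Analytic derivative `dF/dJ` through all three pathways (mean input,
#' effective time constant, and fluctuation scale via the mean voltage), with
#' the rate in the mean-voltage correction held at the evaluated
#' (self-consistent or supplied) rate.
#'
#' @inheritParams siegert_rate
#' @return numeric vector, Hz per unit input.
#' @export
dF_dJ <- function(J, nu_I, par, pop = "E", phi = NULL, delta_L = 0) {
  if (is.null(phi)) phi <- siegert_rate(J, nu_I, par, pop, NULL, delta_L)
  comp <- lif_rate_components(J, nu_I, par, pop, phi, delta_L)
  cp <- comp$cp
  dmu <- (cp$T_E / comp$S) * (par$V_E - par$V_L - comp$mu)
  dtau <- -comp$tau * cp$T_E / comp$S
  lif_rate_derivative(comp, par, dmu, dtau)
}

#' Derivative of the LIF rate with respect to a leak-potential offset
#'
#' Analytic derivative `dF/dDelta_L` for frozen heterogeneity in the leak
#' reversal potential of a neuron: a shift `Delta_L` moves the membrane
#' operating point by `Delta_L / S`, leaving conductances unchanged.
#'
#' @inheritParams siegert_rate
#' @return numeric vector, Hz per mV.
#' @export
dF_dDeltaL <- function(J, nu_I, par, pop = "E", phi = NULL, delta_L = 0) {
  if (is.null(phi)) phi <- siegert_rate(J, nu_I, par, pop, NULL, delta_L)
  comp <- lif_rate_components(J, nu_I, par, pop, phi, delta_L)
  lif_rate_derivative(comp, par, dmu = 1 / comp$S, dtau = 0)
}

#' LIF-derived gain object for the ring network solver
#'
#' Packages the excitatory-population rate function at a fixed inhibitory
#' rate into the `gain` interface used by [solve_bump()], with analytic
#' derivatives with respect to the input and to leak-potential offsets.
#'
#' @param par an [lif_params()] object (tuned).
#' @param nu_I inhibitory rate in the bump state (Hz).
#' @return object of class `gain` with `F`, `dFdJ`, `dFdDeltaL`.
#' @export
lif_gain <- function(par, nu_I) {
  force(par); force(nu_I)
  structure(list(
    F = function(J, phi = NULL) siegert_rate(J, nu_I, par, "E", phi),
    dFdJ = function(J, phi = NULL) dF_dJ(J, nu_I, par, "E", phi),
    dFdDeltaL = function(J, phi = NULL) dF_dDeltaL(J, nu_I, par, "E", phi),
    nu_I = nu_I, par = par, label = "lif"), class = "gain")
}
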