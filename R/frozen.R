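#' Frozen-noise specification
#'
#' Describes one kind of quenched (trial-invariant) heterogeneity:
#' * `"connectivity"`: each ordered pair keeps its synapse with probability
#'   `p` and retained weights are rescaled by `1/p` (autapses are treated
#'   like any other connection, matching the kernel's inclusion of the
#'   diagonal);
#' * `"leak"`: i.i.d. Gaussian offsets (SD `sigma_L`, mV) of each excitatory
#'   neuron's leak reversal potential;
#' * `"weight_jitter"`: additive i.i.d. Gaussian weight noise with SD
#'   `weight_jitter_sd` (kept distinct from the kernel width, which the
#'   weight profile calls `kernel_width`).
#'
#' @param kind one of `"connectivity"`, `"leak"`, `"weight_jitter"`.
#' @param p connection probability (0 < p <= 1).
#' @param sigma_L leak SD (mV, >= 0).
#' @param weight_jitter_sd additive weight SD (>= 0).
#' @param seed integer seed recorded with every realization.
#' @return object of class `frozen_noise`.
#' @export
frozen_noise <- function(kind = c("connectivity", "leak", "weight_jitter"),
                         p = 1, sigma_L = 0, weight_jitter_sd = 0,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(p > 0, p <= 1, sigma_L >= 0, weight_jitter_sd >= 0)
  structure(list(kind = kind, p = p, sigma_L = sigma_L,
                 weight_jitter_sd = weight_jitter_sd,
                 seed = as.integer(seed)),
            class = "frozen_noise")
}

#' Sample one frozen-noise realization
#'
#' @param spec a [frozen_noise()] object.
#' @param N excitatory population size.
#' @return list with `spec` and, depending on kind, `mask` (N x N 0/1),
#'   `jitter` (N x N), or `delta_L` (length-N mV offsets).
#' @export
sample_frozen <- function(spec, N) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  out <- list(spec = spec, N = N)
  if (spec$kind == "connectivity") {
    out$mask <- matrix(stats::rbinom(N * N, 1L, spec$p), N, N)
  } else if (spec$kind == "weight_jitter") {
    out$mask <- matrix(1L, N, N)
    out$jitter <- matrix(stats::rnorm(N * N, 0, spec$weight_jitter_sd), N, N)
  } else {
    out$delta_L <- stats::rnorm(N, 0, spec$sigma_L)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

# steady synaptic activations for the bump centered at every grid position:
# column k holds s0 shifted by k (0-based), i.e. s0_j(phi_k) = s0_{j-k}
shifted_profile_matrix <- function(v) {
  N <- length(v)
  idx <- outer(seq_len(N), 0:(N - 1), function(j, k) ((j - 1 - k) %% N) + 1)
  matrix(v[idx], N, N)
}

#' Structural input perturbation from a frozen realization
#'
#' The extra steady input each excitatory neuron receives, relative to the
#' homogeneous network, when the bump sits at center `phi_k`:
#' \deqn{J^{struct}_i(\varphi_k) = \frac{1}{N}\Big[\frac{1}{p}
#'   \sum_j (w_{ij} + \Delta w_{ij}) m_{ij}\, s_{0,j}(\varphi_k)
#'   - \sum_j w_{ij} s_{0,j}(\varphi_k)\Big].}
#' Its ensemble mean vanishes by construction.
#'
#' @param realization a [sample_frozen()] result (connectivity or
#'   weight-jitter kind).
#' @param bump a [solve_bump()] result (the homogeneous bump).
#' @param weights weight matrix; defaults to the bump's.
#' @return `N x N` matrix, entry `(i, k)` = `J_struct_i(phi_k)` with
#'   `phi_k = 2*pi*(k-1)/N - pi`.
#' @export
struct_input <- function(realization, bump, weights = bump$weights) {
  spec <- realization$spec
  if (spec$kind == "leak")
    stop("struct_input applies to connectivity/weight heterogeneity")
  if (spec$p <= 0) stop("connection probability must be positive")
  N <- bump$N
  S0 <- shifted_profile_matrix(bump$s0)
  Wpert <- weights
  if (!is.null(realization$jitter)) Wpert <- Wpert + realization$jitter
  ((Wpert * realization$mask) %*% S0 / spec$p - weights %*% S0) / N
}

#' First-order rate perturbations induced by frozen noise
#'
#' Linear-response firing-rate deviations from the bump profile for every
#' center position, in bump-centered coordinates: for structural noise
#' `Delta phi_i(phi_k) = phi0'_i * J_struct_{i+k}(phi_k)`, for leak noise
#' `Delta phi_i(phi_k) = (dphi0_i/dDelta_L) * delta_{i+k}` (indices mod N).
#'
#' @param realization a [sample_frozen()] result.
#' @param bump a [solve_bump()] result.
#' @param dF_dDeltaL per-neuron derivative of the rate with respect to a
#'   leak offset (Hz/mV), required for the leak kind; defaults to the bump
#'   gain's `dFdDeltaL` if available.
#' @return `N x N` matrix, entry `(i, k)` = `Delta phi_i(phi_k)`.
#' @export
rate_perturbations <- function(realization, bump, dF_dDeltaL = NULL) {
  N <- bump$N
  spec <- realization$spec
  shift_rows <- function(M) {
    # row i of the output at column k is row ((i+k) mod N) of M's column k
    out <- matrix(0, N, N)
    for (k in 0:(N - 1))
      out[, k + 1] <- M[((seq_len(N) - 1 + k) %% N) + 1, k + 1]
    out
  }
  if (spec$kind == "leak") {
    if (is.null(dF_dDeltaL)) {
      if (is.null(bump$gain$dFdDeltaL))
        stop("leak heterogeneity needs dF_dDeltaL (an LIF gain provides it)")
      dF_dDeltaL <- bump$gain$dFdDeltaL(bump$J0, bump$phi0)
    }
    idx <- outer(seq_len(N) - 1, 0:(N - 1), function(i, k) ((i + k) %% N) + 1)
    dF_dDeltaL * matrix(realization$delta_L[idx], N, N)
  } else {
    Js <- struct_input(realization, bump)
    bump$phi0_prime * shift_rows(Js)
  }
}

#' Drift field induced by a frozen-noise realization
#'
#' Composes [rate_perturbations()] with the theory's drift weights across
#' all center positions.
#'
#' @param realization a [sample_frozen()] result.
#' @param bump a [solve_bump()] result.
#' @param stp an [stp_params()] object; defaults to the bump's.
#' @param theory optional precomputed [attractor_theory()].
#' @param dF_dDeltaL see [rate_perturbations()].
#' @return a [drift_field()] object.
#' @export
drift_field_from_noise <- function(realization, bump, stp = bump$stp,
                                   theory = NULL, dF_dDeltaL = NULL) {
  if (is.null(theory)) theory <- attractor_theory(bump, stp)
  dphi <- rate_perturbations(realization, bump, dF_dDeltaL)
  drift_field_from_perturbation(theory, dphi)
}

#' Ensemble-expected squared drift-field magnitude
#'
#' Closed-form expectation of `A(phi)^2` over the frozen-noise ensemble,
#' independent of the center position:
#' \deqn{\langle A^2\rangle = \sum_i \Big(\frac{C_i}{S}
#'   \frac{dJ_{0,i}}{d\varphi}\Big)^2 \Big[(\phi_{0,i}')^2
#'   \mathrm{Var}[J^{struct}_i] + \Big(\frac{d\phi_{0,i}}{d\Delta_L}\Big)^2
#'   \sigma_L^2\Big],}
#' with \eqn{\mathrm{Var}[J^{struct}_i] = N^{-2}[(1/p - 1)\sum_j w_{ij}^2
#' s_{0,j}^2 + (\sigma_w^2/p) \sum_j s_{0,j}^2]}.
#'
#' @param spec a [frozen_noise()] object (any kind; all terms its parameters
#'   imply are included).
#' @param bump a [solve_bump()] result.
#' @param stp an [stp_params()] object; defaults to the bump's.
#' @param theory optional precomputed [attractor_theory()].
#' @param dF_dDeltaL per-neuron leak derivative (Hz/mV); required if
#'   `sigma_L > 0` and the bump gain lacks `dFdDeltaL`.
#' @return list with `total`, `connectivity` (includes weight jitter) and
#'   `leak` components (rad^2/s^2), plus `N`.
#' @export
expected_sq_field <- function(spec, bump, stp = bump$stp, theory = NULL,
                              dF_dDeltaL = NULL) {
  if (is.null(theory)) theory <- attractor_theory(bump, stp)
  N <- bump$N
  dw2 <- theory$drift_weights^2
  W <- bump$weights
  s0 <- stp_steady_state(bump$phi0, stp)$s
  varJ <- ((1 / spec$p - 1) * as.vector(W^2 %*% s0^2) +
             (spec$weight_jitter_sd^2 / spec$p) * sum(s0^2)) / N^2
  conn <- sum(dw2 * bump$phi0_prime^2 * varJ)
  leak <- 0
  if (spec$sigma_L > 0) {
    if (is.null(dF_dDeltaL)) {
      if (is.null(bump$gain$dFdDeltaL))
        stop("leak heterogeneity needs dF_dDeltaL (an LIF gain provides it)")
      dF_dDeltaL <- bump$gain$dFdDeltaL(bump$J0, bump$phi0)
    }
    leak <- sum(dw2 * dF_dDeltaL^2) * spec$sigma_L^2
  }
  list(total = conn + leak, connectivity = conn, leak = leak, N = N)
}

#' Expected bump displacement over a time horizon
#'
#' Scalar stability summary combining drift and diffusion:
#' \deqn{|\Delta\varphi|(T) = \sqrt{\langle A^2\rangle}\, T + \sqrt{B\,T}.}
#'
#' @param B diffusion strength (rad^2/s, >= 0).
#' @param sq_field expected squared field magnitude (rad^2/s^2, >= 0);
#'   a scalar or the list returned by [expected_sq_field()].
#' @param horizon time horizon (s).
#' @param units `"rad"` or `"deg"`.
#' @return expected displacement.
#' @export
expected_displacement <- function(B, sq_field = 0, horizon = 1,
                                  units = c("rad", "deg")) {
  units <- match.arg(units)
  if (is.list(sq_field)) sq_field <- sq_field$total
  stopifnot(B >= 0, sq_field >= 0)
  d <- sqrt(sq_field) * horizon + sqrt(B * horizon)
  if (units == "deg") d * 180 / pi else d
}

#' Network size achieving a target displacement
#'
#' Smallest excitatory population size `N` whose predicted expected
#' displacement over 1 s is at or below `target_deg`, using the system-size
#' scaling of reference coefficients: diffusion and the leak-drift term
#' scale as `N_ref/N`, the connectivity-drift term as `(N_ref/N)^2`.
#'
#' @param target_deg target displacement (degrees, > 0).
#' @param B_ref diffusion strength at `N_ref` (rad^2/s).
#' @param sq_field_ref [expected_sq_field()] result (or list with
#'   `connectivity` and `leak`) at `N_ref`.
#' @param N_ref reference size.
#' @param horizon time horizon (s).
#' @param N_max search cap.
#' @return integer network size.
#' @export
solve_network_size <- function(target_deg, B_ref, sq_field_ref,
                               N_ref = 800L, horizon = 1, N_max = 1e9) {
  stopifnot(target_deg > 0)
  disp <- function(N) {
    sc <- scale_with_N(B_ref, sq_field_ref$connectivity, sq_field_ref$leak,
                       N_ref, N)
    expected_displacement(sc$B, sc$sq_field, horizon, units = "deg")
  }
  if (disp(N_max) > target_deg)
    stop(sprintf("target %.3g deg unreachable below N = %g", target_deg,
                 N_max))
  lo <- 8; hi <- N_max
  if (disp(lo) <= target_deg) return(as.integer(lo))
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (disp(mid) <= target_deg) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
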