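#' Circular difference of angles
#'
#' Elementwise `a - b` mapped to `(-pi, pi]`.
#'
#' @param a,b angles (rad); recycled.
#' @return numeric vector/matrix of differences.
#' @export
circ_diff <- function(a, b) {
  d <- a - b
  atan2(sin(d), cos(d))
}

#' Population-vector center of a rate profile
#'
#' Phase of the first spatial Fourier coefficient of the firing rates,
#' mapped to the ring coordinates `theta_j = 2*pi*j/N - pi`:
#' `arg(sum_j exp(i 2 pi j / N) nu_j) - pi`, wrapped to `[-pi, pi)`.
#'
#' @param rates numeric vector of per-neuron rates, or a matrix
#'   (times x neurons).
#' @param tol minimum resultant length (relative to total rate) below which
#'   the center is undefined.
#' @return center angle(s) (rad).
#' @export
center_phase <- function(rates, tol = 1e-8) {
  if (is.matrix(rates)) {
    N <- ncol(rates)
    z <- rates %*% exp(1i * 2 * pi * (0:(N - 1)) / N)
    res <- Mod(z) / pmax(rowSums(rates), .Machine$double.xmin)
    if (any(res < tol))
      stop("undefined center: activity profile is (near) uniform")
    return(wrap_angle(Arg(z) - pi))
  }
  N <- length(rates)
  if (!any(rates > 0)) stop("undefined center: no activity")
  z <- sum(rates * exp(1i * 2 * pi * (0:(N - 1)) / N))
  if (Mod(z) / sum(rates) < tol)
    stop("undefined center: activity profile is (near) uniform")
  wrap_angle(Arg(z) - pi)
}

#' Exponentially filtered rates from spike trains
#'
#' Convolves each neuron's spike train with a causal exponential kernel of
#' amplitude `1/kernel_tau` per spike and samples the result on a regular
#' grid.
#'
#' @param spikes data.frame with columns `neuron` (1-based index) and
#'   `t` (s), or a list of per-neuron spike-time vectors.
#' @param n_neurons number of neurons (rows of the output).
#' @param t_max end of the sampling window (s).
#' @param kernel_tau filter time constant (s).
#' @param sample_dt sampling resolution (s).
#' @param t_min start of the sampling window (s).
#' @return matrix (times x neurons) of rates (Hz), with attribute `times`.
#' @export
rates_from_spikes <- function(spikes, n_neurons, t_max, kernel_tau = 0.1,
                              sample_dt = 0.001, t_min = 0) {
  if (is.data.frame(spikes)) {
    spikes <- split(spikes$t, factor(spikes$neuron, levels = seq_len(n_neurons)))
  }
  times <- seq(t_min, t_max, by = sample_dt)
  decay <- exp(-sample_dt / kernel_tau)
  out <- matrix(0, length(times), n_neurons)
  for (j in seq_len(n_neurons)) {
    st <- spikes[[j]]
    st <- st[st <= t_max]
    if (!length(st)) next
    # exact contribution of each spike at the first grid point at/after it,
    # then recursive exponential decay
    counts <- numeric(length(times))
    k <- pmin(pmax(ceiling((st - t_min) / sample_dt - 1e-12), 0) + 1L,
              length(times))
    add <- exp(-(times[k] - st) / kernel_tau) / kernel_tau
    for (i in seq_along(k)) counts[k[i]] <- counts[k[i]] + add[i]
    out[, j] <- as.numeric(stats::filter(counts, decay, method = "recursive"))
  }
  attr(out, "times") <- times
  out
}

#' Estimate the diffusion strength from an ensemble of trajectories
#'
#' Regression-based estimate: squared displacements from the position at
#' `discard` seconds are averaged over repetitions, and the slope of the
#' linear fit of this variance against elapsed time (with intercept, to
#' absorb initial transients) estimates the diffusion strength.  The
#' confidence interval resamples whole trajectories with replacement and
#' uses the bias-corrected accelerated (BCa) bootstrap.
#'
#' @param trajectories a [langevin_ensemble()]-style `trajectory_set`, or a
#'   matrix (reps x times) with a `times` argument.
#' @param times sample times (s), if `trajectories` is a matrix.
#' @param discard initial interval discarded as transient (s).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param ci `"bca"` (default) or `"jackknife"`.
#' @return object of class `diffusion_estimate`: list with `slope`
#'   (rad^2/s), `intercept`, `ci_low`, `ci_high`, `n_reps`.
#' @export
estimate_diffusion <- function(trajectories, times = NULL, discard = 0.5,
                               n_boot = 5000L, conf = 0.95,
                               ci = c("bca", "jackknife")) {
  ci <- match.arg(ci)
  if (inherits(trajectories, "trajectory_set")) {
    times <- trajectories$times
    phi <- trajectories$phi
  } else phi <- trajectories
  stopifnot(is.matrix(phi), length(times) == ncol(phi))
  if (nrow(phi) < 2L) stop("need at least 2 trajectories")
  if (nrow(phi) < 10L)
    warning("fewer than 10 trajectories: confidence interval unreliable")
  i0 <- which.min(abs(times - discard))
  keep <- i0:ncol(phi)
  tt <- times[keep] - times[i0]
  D2 <- circ_diff(phi[, keep, drop = FALSE], phi[, i0])^2
  slope_of <- function(v) {
    ct <- tt - mean(tt)
    sum(ct * (v - mean(v))) / sum(ct^2)
  }
  fit_of <- function(idx) slope_of(colMeans(D2[idx, , drop = FALSE]))
  V <- colMeans(D2)
  slope <- slope_of(V)
  intercept <- mean(V) - slope * mean(tt)
  K <- nrow(phi)
  if (ci == "bca") {
    bt <- boot::boot(seq_len(K),
                     function(d, i) fit_of(d[i]),
                     R = n_boot)
    bci <- tryCatch(boot::boot.ci(bt, conf = conf, type = "bca"),
                    error = function(e) NULL)
    if (!is.null(bci)) {
      lo <- bci$bca[4L]; hi <- bci$bca[5L]
    } else {
      q <- stats::quantile(bt$t, c((1 - conf) / 2, (1 + conf) / 2))
      lo <- q[1L]; hi <- q[2L]
    }
  } else {
    jack <- vapply(seq_len(K), function(k) fit_of(setdiff(seq_len(K), k)),
                   numeric(1))
    se <- sqrt((K - 1) / K * sum((jack - mean(jack))^2))
    zc <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- slope - zc * se; hi <- slope + zc * se
  }
  structure(list(slope = slope, intercept = intercept,
                 ci_low = lo, ci_high = hi, n_reps = K, conf = conf),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "Diffusion estimate: slope %.4g rad^2/s (%.0f%% CI %.4g..%.4g, %d reps)\n",
    x$slope, 100 * x$conf, x$ci_low, x$ci_high, x$n_reps))
  invisible(x)
}

#' Estimate the drift field from trajectories
#'
#' Discrete velocity estimates `(phi(t0 + (j+1) lag) - phi(t0 + j lag))/lag`
#' (circular differences, hence bounded by `pi/lag`) collected over a grid
#' of start offsets, binned by the position at the interval start.
#'
#' @param trajectories `trajectory_set` or matrix (reps x times).
#' @param times sample times if a matrix is given.
#' @param lag velocity lag (s).
#' @param t0_grid start offsets (s).
#' @param bins number of left-closed bins on `[-pi, pi)`.
#' @return list with `centers` (bin midpoints), `A` (binned mean velocity,
#'   `NA` for empty bins), `n` (points per bin), and `raw` (data.frame with
#'   `phi`, `v`).
#' @export
estimate_drift_field <- function(trajectories, times = NULL, lag = 1.5,
                                 t0_grid = seq(0.5, 1.9, by = 0.2),
                                 bins = 100L) {
  if (inherits(trajectories, "trajectory_set")) {
    times <- trajectories$times
    phi <- trajectories$phi
  } else phi <- trajectories
  t_max <- max(times)
  at <- function(tq) phi[, vapply(tq, function(t) which.min(abs(times - t)),
                                  integer(1)), drop = FALSE]
  pos <- NULL; vel <- NULL
  for (t0 in t0_grid) {
    tj <- seq(t0, t_max - lag + 1e-9, by = lag)
    if (!length(tj)) next
    p1 <- at(tj); p2 <- at(tj + lag)
    pos <- c(pos, as.vector(p1))
    vel <- c(vel, as.vector(circ_diff(p2, p1)) / lag)
  }
  if (is.null(pos)) stop("trajectories shorter than t0 + lag")
  br <- seq(-pi, pi, length.out = bins + 1L)
  bin <- findInterval(pos, br, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > bins] <- bins
  A <- tapply(vel, factor(bin, levels = seq_len(bins)), mean)
  n <- tapply(vel, factor(bin, levels = seq_len(bins)), length)
  list(centers = (br[-1L] + br[-(bins + 1L)]) / 2,
       A = as.vector(A), n = as.integer(ifelse(is.na(n), 0L, n)),
       raw = data.frame(phi = pos, v = vel))
}

#' Flag repetitions whose bump state collapsed
#'
#' A repetition is dropped when the population-maximal firing rate falls
#' below `threshold` at any sampled time during the delay window.
#'
#' @param max_rates matrix (reps x times) of population-max rates (Hz), or a
#'   vector per repetition of minima already taken over time.
#' @param threshold rate threshold (Hz).
#' @return logical vector, `TRUE` = keep.
#' @export
exclude_lost_bumps <- function(max_rates, threshold = 10) {
  m <- if (is.matrix(max_rates)) apply(max_rates, 1L, min) else max_rates
  m >= threshold
}

#' Mutual information between initial and final bump positions
#'
#' Plug-in estimate on joint and marginal histograms over `[-pi, pi)`:
#' \deqn{MI = \sum_{ij} r_{ij} \log_2 \frac{r_{ij}}{p_i q_j}.}
#' No bias correction is applied; when a `reference` MI is supplied the
#' ratio `relative_mi` is reported, which is nearly invariant under a change
#' of bin number.
#'
#' @param start,end paired angle samples (rad).
#' @param bins number of bins.
#' @param reference optional reference MI (bits) for normalization.
#' @return object of class `mi_result`: list with `mi_bits`, `n_bins`,
#'   `relative_mi` (or `NA`).
#' @export
mutual_information <- function(start, end, bins = 100L, reference = NULL) {
  stopifnot(length(start) == length(end))
  br <- seq(-pi, pi, length.out = bins + 1L)
  cut2 <- function(x) {
    b <- findInterval(wrap_angle(x), br, left.open = FALSE)
    pmin(pmax(b, 1L), bins)
  }
  r <- table(factor(cut2(start), levels = seq_len(bins)),
             factor(cut2(end), levels = seq_len(bins)))
  r <- r / sum(r)
  p <- rowSums(r); q <- colSums(r)
  nz <- r > 0
  mi <- sum(r[nz] * log2(r[nz] / (p[row(r)[nz]] * q[col(r)[nz]])))
  structure(list(mi_bits = mi, n_bins = bins,
                 relative_mi = if (is.null(reference)) NA_real_ else
                   mi / reference),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Mutual information: %.4g bits (%d bins)%s\n", x$mi_bits,
              x$n_bins,
              if (is.na(x$relative_mi)) "" else
                sprintf(", relative %.3f", x$relative_mi)))
  invisible(x)
}

#' Distractor sensitivity of the stored bump
#'
#' Predicts the displacement of a bump (initialized at 0) caused by a
#' transient localized distractor input: neurons in a window of
#' `width_neurons` around each probe position fire at rates elevated by
#' `delta_rate`, the induced drift field follows from the theory's drift
#' weights, and the center dynamics are integrated for `duration` with the
#' network's diffusion.
#'
#' @param theory an [attractor_theory()] object.
#' @param phi_D probe distractor positions (rad).
#' @param delta_rate rate elevation (Hz).
#' @param width_neurons width of the stimulated window (neurons).
#' @param duration stimulus duration (s).
#' @param dt integration step (s).
#' @param n_reps trajectories per probe position.
#' @param seed RNG seed.
#' @return data.frame with columns `phi_D`, `mean_final`, `sd_final`.
#' @export
distractor_experiment <- function(theory, phi_D = seq(-pi, pi, length.out = 33),
                                  delta_rate = 20, width_neurons = 40L,
                                  duration = 0.25, dt = 0.01,
                                  n_reps = 1000L, seed = 1L) {
  N <- theory$N
  dw <- theory$drift_weights
  half <- width_neurons / 2
  th <- 2 * pi * (0:(N - 1)) / N - pi
  set.seed(seed)
  res <- lapply(phi_D, function(pd) {
    # boxcar rate elevation, fixed in lab coordinates
    j <- which.min(abs(circ_diff(th, pd)))
    dist_idx <- abs(circ_diff(th, th[j])) <= (half + 0.1) * 2 * pi / N
    P <- ifelse(dist_idx, delta_rate, 0)
    # bump-frame perturbation at center k is the lab pattern shifted by k
    idx <- outer(seq_len(N) - 1, 0:(N - 1), function(i, k) ((i + k) %% N) + 1)
    dphi <- matrix(P[idx], N, N)
    fld <- drift_field_from_perturbation(theory, dphi)
    ens <- langevin_ensemble(theory$B, fld, t_max = duration, dt = dt,
                             phi0 = 0, n_reps = n_reps)
    fin <- ens$phi[, ncol(ens$phi)]
    data.frame(phi_D = pd, mean_final = mean(fin), sd_final = stats::sd(fin))
  })
  do.call(rbind, res)
}
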