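test_that("population-vector center decodes positions on the ring", {
  N <- 128
  th <- ring_geometry(N)$theta
  for (j in c(1, 40, 100)) {
    v <- rep(0, N); v[j] <- 10
    expect_equal(center_phase(v), th[j], tolerance = 1e-12)
  }
  bump <- generalized_gaussian_profile(th - 0.7)
  expect_lt(abs(center_phase(bump) - 0.7), 2 * pi / N)
  expect_error(center_phase(rep(1, N)), "uniform")
  expect_error(center_phase(rep(0, N)), "center")
  # matrix input decodes row-wise
  M <- rbind(generalized_gaussian_profile(th - 0.7),
             generalized_gaussian_profile(th + 1.1))
  expect_equal(as.vector(center_phase(M)), c(0.7, -1.1), tolerance = 0.05)
})

test_that("exponential rate filter has unit area and recovers Poisson rates", {
  sp <- data.frame(neuron = 1L, t = 0.2)
  r <- rates_from_spikes(sp, n_neurons = 2, t_max = 1, kernel_tau = 0.1,
                         sample_dt = 0.001)
  tt <- attr(r, "times")
  after <- tt >= 0.2
  expect_equal(r[after, 1], exp(-(tt[after] - 0.2) / 0.1) / 0.1,
               tolerance = 1e-6)
  expect_equal(max(abs(r[, 2])), 0)   # empty train stays zero
  set.seed(2)
  spikes <- data.frame(neuron = 1L, t = sort(stats::runif(4000, 0, 100)))
  rr <- rates_from_spikes(spikes, 1, t_max = 100, sample_dt = 0.005)
  expect_lt(abs(mean(rr[attr(rr, "times") > 1, 1]) - 40), 3)
})

test_that("diffusion estimator recovers a known Langevin coefficient", {
  ens <- langevin_ensemble(0.01, 0, t_max = 5, dt = 0.1, n_reps = 500,
                           seed = 21)
  est <- estimate_diffusion(ens, discard = 0.5, n_boot = 1000)
  expect_gt(0.01, est$ci_low)
  expect_lt(0.01, est$ci_high)
  expect_lt(abs(est$slope - 0.01) / 0.01, 0.2)
  # zero-noise trajectories give exactly zero slope and intercept
  ens0 <- langevin_ensemble(0, 0, t_max = 3, dt = 0.1,
                            phi0 = c(0.1, -0.4, 1), n_reps = 3)
  est0 <- suppressWarnings(estimate_diffusion(ens0, n_boot = 50))
  expect_equal(est0$slope, 0)
  expect_equal(est0$intercept, 0)
  # duplicating the set keeps the point estimate, tightens the interval
  dup <- structure(list(times = ens$times, phi = rbind(ens$phi, ens$phi)),
                   class = "trajectory_set")
  estd <- estimate_diffusion(dup, discard = 0.5, n_boot = 1000)
  expect_equal(estd$slope, est$slope, tolerance = 1e-12)
  expect_lt(estd$ci_high - estd$ci_low, est$ci_high - est$ci_low)
  # jackknife agrees with the bootstrap to first order
  estj <- estimate_diffusion(ens, discard = 0.5, ci = "jackknife")
  expect_lt(abs(estj$ci_high - est$ci_high) / (est$ci_high - est$ci_low), 0.5)
})

test_that("diffusion estimator is unbiased over repeated synthetic ensembles", {
  slopes <- vapply(1:20, function(k) {
    ens <- langevin_ensemble(0.02, 0, t_max = 4, dt = 0.05, n_reps = 400,
                             seed = 300 + k)
    estimate_diffusion(ens, discard = 0.5, n_boot = 0, ci = "jackknife")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.02) / 0.02, 0.02)
})

test_that("drift-field estimator recovers a known field and handles the wrap", {
  N <- 64
  th <- 2 * pi * (0:(N - 1)) / N - pi
  A_true <- 0.25 * sin(th)
  ens <- langevin_ensemble(0.004, drift_field(th, A_true), t_max = 8,
                           dt = 0.05,
                           phi0 = seq(-pi, pi, length.out = 41)[1:40],
                           n_reps = 400, seed = 31)
  est <- estimate_drift_field(ens, lag = 1.5, bins = 40)
  f <- interpolate_field(drift_field(th, A_true))
  ok <- !is.na(est$A)
  truth <- f(est$centers[ok])
  steep <- abs(truth) > 0.8 * max(abs(truth))
  rmse <- sqrt(mean((est$A[ok][!steep] - truth[!steep])^2))
  expect_lt(rmse / max(abs(A_true)), 0.15)
  # drift-free ensemble: all bins statistically zero
  ens0 <- langevin_ensemble(0.004, 0, t_max = 8, dt = 0.05,
                            phi0 = seq(-pi, pi, length.out = 41)[1:40],
                            n_reps = 200, seed = 32)
  est0 <- estimate_drift_field(ens0, lag = 1.5, bins = 20)
  se <- sqrt(0.004 / 1.5) / sqrt(pmax(est0$n, 1))
  expect_lt(max(abs(est0$A / se), na.rm = TRUE), 5)
  # differences are taken on the circle: no +-2pi spikes near the wrap
  drift <- drift_field(th, rep(1.5, N))
  ens2 <- langevin_ensemble(0, drift, t_max = 6, dt = 0.05, phi0 = -3,
                            n_reps = 2)
  est2 <- estimate_drift_field(ens2, lag = 1.5, bins = 10)
  expect_lt(max(abs(est2$A), na.rm = TRUE), 2)
})

test_that("lost-bump exclusion flags exactly the collapsed repetitions", {
  times <- seq(0, 5, by = 0.1)
  healthy <- matrix(40 + stats::rnorm(5 * length(times), 0, 2), nrow = 5)
  lost <- healthy
  lost[2, 30:35] <- 0.5
  lost[5, 51] <- 9.9
  keep <- exclude_lost_bumps(lost)
  expect_equal(which(!keep), c(2L, 5L))
  expect_true(all(exclude_lost_bumps(healthy)))
})

test_that("mutual information matches closed forms and is well-behaved", {
  # identity channel over k occupied bins: MI = log2(k)
  x <- rep(seq(-3, 3, length.out = 12), each = 30)
  expect_equal(mutual_information(x, x, bins = 100)$mi_bits, log2(12),
               tolerance = 1e-12)
  # independent pairs: MI below the plug-in bias bound
  set.seed(4)
  n <- 20000
  a <- stats::runif(n, -pi, pi); b <- stats::runif(n, -pi, pi)
  mi_ind <- mutual_information(a, b, bins = 50)$mi_bits
  expect_lt(mi_ind, (50 - 1)^2 / (2 * n * log(2)) * 1.5)
  # symmetry and rotation invariance
  y <- wrap_angle(x + 0.3 + stats::rnorm(length(x), 0, 0.1))
  expect_equal(mutual_information(x, y, bins = 40)$mi_bits,
               mutual_information(y, x, bins = 40)$mi_bits)
  expect_equal(mutual_information(wrap_angle(x + 1), wrap_angle(y + 1),
                                  bins = 40)$mi_bits,
               mutual_information(x, y, bins = 40)$mi_bits,
               tolerance = 0.2)
  # diffusion strictly degrades the channel
  starts <- rep(seq(-pi, pi - 0.3, length.out = 20), each = 50)
  noisy <- wrap_angle(starts + stats::rnorm(length(starts), 0, 0.6))
  expect_lt(mutual_information(starts, noisy)$mi_bits,
            mutual_information(starts, starts)$mi_bits)
  mi_rel <- mutual_information(starts, noisy, reference = 2)$relative_mi
  expect_equal(mi_rel, mutual_information(starts, noisy)$mi_bits / 2)
})

test_that("distractor displacement is odd in position and bounded by diffusion", {
  toy <- toy_fixture()
  th <- attractor_theory(toy$bump)
  # distractor window scaled to the toy ring (40 neurons at N = 800
  # corresponds to ~0.3 rad, i.e. 4 neurons at N = 64)
  res <- distractor_experiment(th, phi_D = c(-2.7, -0.6, 0, 0.6, 2.7),
                               width_neurons = 4, n_reps = 400, seed = 3)
  # on top of the bump: no net displacement
  sem <- res$sd_final / sqrt(400)
  expect_lt(abs(res$mean_final[res$phi_D == 0]), 3 * sem[res$phi_D == 0])
  # odd symmetry of the mean displacement
  expect_lt(abs(res$mean_final[2] + res$mean_final[4]),
            4 * sqrt(sem[2]^2 + sem[4]^2) + 0.02)
  # with no rate elevation the spread is pure diffusion
  res0 <- distractor_experiment(th, phi_D = 0.5, delta_rate = 0,
                                width_neurons = 4, n_reps = 400, seed = 3)
  expect_lt(abs(res0$sd_final - sqrt(th$B * 0.25)) / sqrt(th$B * 0.25), 0.15)
  # facilitation reduces the maximal displacement (fixed bump shape)
  sweep_max <- vapply(c(1, 0.1), function(U) {
    thU <- attractor_theory(toy$bump, stp_params(U, 0.65, 0.15, 0.1))
    r <- distractor_experiment(thU, phi_D = seq(0.2, 1.6, by = 0.2),
                               width_neurons = 4, n_reps = 150, seed = 9)
    max(abs(r$mean_final))
  }, numeric(1))
  expect_lt(sweep_max[2], sweep_max[1])
})
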