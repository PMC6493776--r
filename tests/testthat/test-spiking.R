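test_that("spiking simulation is deterministic and respects refractoriness", {
  ref <- ref_fixture()
  cfg <- spiking_config(ref$par, ref$stp, N_E = 100, N_I = 25, t_max = 1.5,
                        protocol = "cue", cue_phi = 0, seed = 3, dt = 1e-4)
  s1 <- simulate_spiking(cfg)
  s2 <- simulate_spiking(cfg)
  expect_identical(s1$spikes_E, s2$spikes_E)
  expect_identical(s1$spikes_I, s2$spikes_I)
  isi_ok <- vapply(split(s1$spikes_E$t, s1$spikes_E$neuron), function(ts)
    length(ts) < 2 || min(diff(sort(ts))) >= ref$par$tau_ref_E - 1e-9,
    logical(1))
  expect_true(all(isi_ok))
  isi_okI <- vapply(split(s1$spikes_I$t, s1$spikes_I$neuron), function(ts)
    length(ts) < 2 || min(diff(sort(ts))) >= ref$par$tau_ref_I - 1e-9,
    logical(1))
  expect_true(all(isi_okI))
})

test_that("a bump-initialized delay period sustains a localized state", {
  ref <- ref_fixture()
  N_E <- 200L
  W <- ring_kernel(ring_geometry(N_E), ref$par$w_plus, ref$par$kernel_width)
  b <- solve_bump(W, ref$gain, ref$stp,
                  init = generalized_gaussian_profile(ring_geometry(N_E)),
                  method = "newton", tol = 1e-8)
  cfg <- spiking_config(ref$par, ref$stp, N_E = N_E, N_I = 50L, t_max = 2.5,
                        protocol = "uncued", seed = 101, dt = 5e-5,
                        init_bump = b)
  cfg$t_off <- 0
  sim <- simulate_spiking(cfg)
  late <- sim$times > 1.5
  # alive, localized, and with a quiet background
  expect_gt(stats::median(sim$maxrate[late]), 20)
  mr <- spiking_mean_rates(sim, c(1, 2.5))
  expect_gt(max(mr$nu_E), 25)
  expect_lt(stats::median(mr$nu_E), 3)
  # center stays defined and moves diffusively, not ballistically
  expect_true(all(is.finite(sim$center[late])))
})

test_that("the uncued network stays non-selective at low rates", {
  ref <- ref_fixture()
  cfg <- spiking_config(ref$par, ref$stp, N_E = 200L, N_I = 50L, t_max = 3,
                        protocol = "uncued", seed = 5, dt = 5e-5)
  sim <- simulate_spiking(cfg)
  mr <- spiking_mean_rates(sim, c(0.5, 1.5))
  # excitatory rates stay far below the bump regime; inhibitory rates near
  # their basal target
  expect_lt(max(mr$nu_E), 10)
  expect_lt(abs(mr$nu_I - 3) / 3, 0.5)
})

test_that("frozen-synapse transmission reduces to constant release", {
  ref <- ref_fixture()
  cfg <- spiking_config(ref$par, ref$stp, N_E = 60L, N_I = 15L, t_max = 0.8,
                        protocol = "uncued", seed = 7, dt = 1e-4,
                        stp_frozen = TRUE)
  simf <- simulate_spiking(cfg)
  # same seed, same network with plasticity active: basal spiking is sparse
  # enough that both transmit near the baseline release, so population
  # activity stays comparable, but the runs are not identical
  cfg2 <- cfg; cfg2$stp_frozen <- FALSE
  sim <- simulate_spiking(cfg2)
  expect_true(nrow(simf$spikes_I) > 0)
  expect_lt(abs(nrow(simf$spikes_I) - nrow(sim$spikes_I)) /
              max(1, nrow(sim$spikes_I)), 0.5)
})

test_that("reset input returns a bump-initialized network to rest", {
  ref <- ref_fixture()
  N_E <- 200L
  W <- ring_kernel(ring_geometry(N_E), ref$par$w_plus, ref$par$kernel_width)
  b <- solve_bump(W, ref$gain, ref$stp,
                  init = generalized_gaussian_profile(ring_geometry(N_E)),
                  method = "newton", tol = 1e-8)
  cfg <- spiking_config(ref$par, ref$stp, N_E = N_E, N_I = 50L, t_max = 3,
                        protocol = "reset_after_cue", reset_at = 1.2,
                        seed = 11, dt = 5e-5, init_bump = b,
                        t_initial = -1.5)  # no cue phase: stim rows before 0
  cfg$stim <- cfg$stim[3, , drop = FALSE]
  cfg$stim_target <- cfg$stim_target[, 3, drop = FALSE]
  cfg$t_off <- 0
  sim <- simulate_spiking(cfg)
  pre <- sim$times > 0.5 & sim$times < 1.1
  post <- sim$times > 2.2
  expect_gt(stats::median(sim$maxrate[pre]), 20)   # bump alive before reset
  expect_lt(stats::median(sim$maxrate[post]), 10)  # non-selective after
})
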