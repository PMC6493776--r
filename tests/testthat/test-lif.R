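test_that("rate prediction respects the refractory ceiling and monotonicity", {
  par <- lif_params(g_EE = 50, g_EI = 600, g_IE = 10, g_II = 80)
  J <- seq(0, 2, length.out = 15)
  Fr <- siegert_rate(J, nu_I = 5, par)
  expect_true(all(Fr <= 1 / par$tau_ref_E + 1e-9))
  expect_true(all(Fr > 0))
  expect_true(all(diff(Fr) > 0))
})

test_that("analytic derivatives match finite differences at random points", {
  par <- lif_params(g_EE = 50, g_EI = 600, g_IE = 10, g_II = 80)
  set.seed(20)
  J <- stats::runif(50, 0, 1.2)
  nu_I <- stats::runif(1, 2, 8)
  phi <- siegert_rate(J, nu_I, par)
  h <- 1e-7
  fd <- (bumpdrift:::lif_rate_components(J + h, nu_I, par, "E", phi)$F -
           bumpdrift:::lif_rate_components(J - h, nu_I, par, "E", phi)$F) /
    (2 * h)
  an <- dF_dJ(J, nu_I, par, phi = phi)
  expect_lt(max(abs(fd - an) / abs(fd)), 1e-4)
  hL <- 1e-5
  fdL <- (bumpdrift:::lif_rate_components(J, nu_I, par, "E", phi,
                                          delta_L = hL)$F -
            bumpdrift:::lif_rate_components(J, nu_I, par, "E", phi,
                                            delta_L = -hL)$F) / (2 * hL)
  anL <- dF_dDeltaL(J, nu_I, par, phi = phi)
  expect_lt(max(abs(fdL - anL) / abs(fdL)), 1e-4)
  # depolarizing leak shifts always raise the rate
  expect_true(all(anL > 0))
})

test_that("rate formula agrees with a Monte-Carlo neuron where it applies", {
  # moderate-rate, mean-driven-to-fluctuation transition point: the
  # diffusion approximation is accurate here (its known bias grows only in
  # the deeply subthreshold tail)
  ref <- ref_fixture()
  par <- ref$par
  b <- ref$bump
  j <- which.min(abs(circ_diff(b$theta, b$center + 0.35)))  # mid flank
  target <- b$phi0[j]
  cp <- bumpdrift:::lif_composites(par, "E")
  set.seed(33)
  mc <- bumpdrift:::mc_lif_rate_cpp(
    par$Cm_E, par$gL_E, par$V_L, par$V_E, par$V_I, par$V_thr, par$V_res,
    par$tau_ref_E, par$tau_ext, par$g_ext_E, par$N_ext * par$nu_ext,
    cp$T_E * b$J0[j] * par$gL_E, cp$T_I * ref$nu_I * par$gL_E,
    T = 150, dt = 2e-5)
  pred <- bumpdrift:::lif_rate_components(b$J0[j], ref$nu_I, par, "E",
                                          phi = target)$F
  expect_lt(abs(mc - pred) / pred, 0.10)
})

test_that("tuned network satisfies its target equations", {
  ref <- ref_fixture()
  par <- ref$par
  stp <- ref$stp
  # basal state self-consistency at the targets
  J_b <- par$tau_E * poisson_mean_ux(0.5, stp) * 0.5
  expect_lt(abs(siegert_rate(J_b, 3, par, "E", phi = 0.5) - 0.5), 1e-6)
  expect_lt(abs(siegert_rate(par$tau_E * 0.5, 3, par, "I", phi = 3) - 3),
            1e-6)
  # collocation residuals on the bump body
  res <- attr(par, "residuals")
  expect_lt(max(abs(res[1:3])), 1e-6)
  # inhibitory self-consistency at the realized bump
  FI <- siegert_rate(par$tau_E * mean(ref$bump$phi0), ref$nu_I, par, "I",
                     phi = ref$nu_I)
  expect_lt(abs(FI - ref$nu_I), 1e-6)
})

test_that("realized reference bump matches the target parametrization", {
  ref <- ref_fixture()
  expect_lt(abs(max(ref$bump$phi0) - 40.1) / 40.1, 0.1)
  expect_lt(abs(ref$fit[["g_sigma"]] - 0.5), 0.05)
  expect_lt(abs(ref$fit[["g1"]] - 40), 2)
  expect_lt(ref$bump$residual, 1e-7)
  # gain slope is positive on the bump
  expect_true(all(ref$bump$phi0_prime > 0))
})

test_that("retuning under strong facilitation keeps the bump comparable", {
  ref1 <- ref_fixture()
  refF <- reference_network(stp = stp_params(0.4, 0.65, 0.15, 0.1))
  expect_lt(abs(max(refF$bump$phi0) - max(ref1$bump$phi0)) /
              max(ref1$bump$phi0), 0.15)
  # conductances differ between the two tunings
  expect_gt(abs(refF$par$g_EE - ref1$par$g_EE) / ref1$par$g_EE, 0.01)
})
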