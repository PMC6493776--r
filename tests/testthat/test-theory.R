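test_that("the translation mode is a null vector of the assembled Jacobian", {
  toy <- toy_fixture()
  lin <- build_K(toy$bump)
  expect_lt(max(abs(lin$K %*% lin$e_r)) / max(abs(lin$e_r)), 1e-6)
})

test_that("closed-form coefficients match the numeric null projection", {
  toy <- toy_fixture()
  th <- attractor_theory(toy$bump)
  np <- numeric_null_projection(toy$bump)
  expect_rel_equal(th$B, np$B, 1e-8)
  expect_rel_equal(th$S, np$S, 1e-6)
  expect_lt(max(abs(th$drift_weights - np$drift_weights)) /
              max(abs(np$drift_weights)), 1e-8)
  # first N components of the left null vector align with dJ0/dphi
  N <- toy$bump$N
  els <- np$e_l[1:N]
  cs <- sum(els * toy$bump$dJ0_dphi) /
    sqrt(sum(els^2) * sum(toy$bump$dJ0_dphi^2))
  expect_gt(cs, 1 - 1e-8)
  # normalization contract
  expect_lt(abs(sum(np$e_l * build_K(toy$bump)$e_r) - 1), 1e-10)
})

test_that("static-synapse limit recovers C_i = 1 and S = tau_s sum (dJ')^2 phi'", {
  toy <- toy_fixture()
  stp_static <- stp_params(U = 1, tau_u = 1e-9, tau_x = 0, tau_s = 0.1)
  pf <- prefactors(toy$bump, stp_static)
  expect_lt(max(abs(pf$C - 1)), 1e-10)
  S_static <- 0.1 * sum(toy$bump$dJ0_dphi^2 * toy$bump$phi0_prime)
  expect_rel_equal(pf$S, S_static, 1e-10)
})

test_that("strong-facilitation limit loses its depression dependence", {
  toy <- toy_fixture()
  phi0 <- toy$bump$phi0
  tau_u <- 0.65; tau_s <- 0.1
  U <- 1e-7
  for (tau_x in c(0.05, 0.25)) {
    pf <- prefactors(toy$bump, stp_params(U, tau_u, tau_x, tau_s))
    # printed limit: C/S -> (1 + 2 tau_u phi) / sum((dJ')^2 phi'
    #   [tau_s (1 + 2 tau_u phi) + tau_u^2 phi])
    CS_lim <- (1 + 2 * tau_u * phi0) /
      sum(toy$bump$dJ0_dphi^2 * toy$bump$phi0_prime *
            (tau_s * (1 + 2 * tau_u * phi0) + tau_u^2 * phi0))
    expect_rel_equal(pf$C / pf$S, CS_lim, 5e-4)
  }
})

test_that("oracle equivalence holds across random STP parameter sets", {
  set.seed(7)
  W <- ring_kernel(ring_geometry(64), w_plus = 14, kernel_width = 0.5)
  for (k in 1:3) {
    stp <- stp_params(runif(1, 0.3, 1), runif(1, 0.2, 1), runif(1, 0.12, 0.2),
                      0.1)
    b <- solve_bump(W, gain_softplus(), stp, tol = 1e-12, max_iter = 50000L)
    th <- attractor_theory(b)
    np <- numeric_null_projection(b)
    expect_rel_equal(th$B, np$B, 1e-8)
  }
})

test_that("drift fields from perturbations obey parity and linearity", {
  toy <- toy_fixture()
  th <- attractor_theory(toy$bump)
  N <- toy$bump$N
  # zero perturbation: zero field
  expect_equal(drift_field_from_perturbation(th, rep(0, N))$A, rep(0, N))
  # even-symmetric perturbation about the center gives zero velocity there
  ic <- which.max(toy$bump$phi0)
  d <- abs(circ_diff(toy$bump$theta, toy$bump$theta[ic]))
  dphi_even <- 5 * exp(-d^2 / 0.2)
  A0 <- sum(th$drift_weights * dphi_even)
  expect_lt(abs(A0), 1e-8 * max(abs(th$drift_weights)) * 5 * N)
  # excitation on the left flank pulls the bump left
  dphi <- rep(0, N); dphi[ic - 5] <- 5
  expect_lt(sum(th$drift_weights * dphi), 0)
  dphi_r <- rep(0, N); dphi_r[ic + 5] <- 5
  expect_gt(sum(th$drift_weights * dphi_r), 0)
})

test_that("critical depression time exists and grows with facilitation", {
  toy <- toy_fixture()
  tx_c <- vapply(c(1, 0.6, 0.3), function(U)
    critical_tau_x(toy$bump, stp_params(U, 1e-6, 0.15, 0.1)), numeric(1))
  expect_true(all(tx_c > 0))
  expect_true(all(diff(tx_c) > 0))  # stronger facilitation -> larger tau_x,c
  # S is positive below and negative above the root
  stp_lo <- stp_params(1, 1e-6, 0.9 * tx_c[1], 0.1)
  stp_hi <- stp_params(1, 1e-6, 1.1 * tx_c[1], 0.1)
  expect_gt(prefactors(toy$bump, stp_lo)$S, 0)
  expect_lt(prefactors(toy$bump, stp_hi)$S, 0)
  expect_error(attractor_theory(toy$bump, stp_hi), "critical")
})

test_that("diffusion strength scales as 1/N and drift terms as prescribed", {
  sc <- scale_with_N(B = 0.02, sq_field_connectivity = 1e-4,
                     sq_field_leak = 4e-4, N_ref = 800, N = 800)
  expect_equal(sc$B, 0.02)
  expect_equal(sc$sq_field, 5e-4)
  sc2 <- scale_with_N(0.02, 1e-4, 4e-4, 800, 1600)
  expect_equal(sc2$B, 0.01)
  expect_equal(sc2$sq_field_connectivity, 2.5e-5)
  expect_equal(sc2$sq_field_leak, 2e-4)
  # re-discretizing the same smooth network at 2N matches the scaling law
  toy64 <- toy_fixture()
  toy128 <- toy_fixture_128()
  B64 <- attractor_theory(toy64$bump)$B
  B128 <- attractor_theory(toy128$bump)$B
  expect_rel_equal(B128, scale_with_N(B64, 0, 0, 64, 128)$B, 0.01)
})

test_that("diffusion decreases with facilitation and increases with depression", {
  toy <- toy_fixture()
  B_of <- function(U, tx) attractor_theory(toy$bump,
                                           stp_params(U, 0.65, tx, 0.1))$B
  BU <- vapply(c(1, 0.7, 0.4, 0.1), B_of, tx = 0.15, numeric(1))
  expect_true(all(diff(BU) < 0))
  Btx <- vapply(c(0.12, 0.16, 0.2), function(tx) B_of(0.8, tx), numeric(1))
  expect_true(all(diff(Btx) > 0))
})
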