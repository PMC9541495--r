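test_that("tight-binding quadratic limits and oracle agreement", {
  # infinitely tight: all tracer bound
  expect_equal(bound_ligand_quadratic(0, 1e-6, 5e-8), 5e-8)
  # no binding limit
  expect_lt(bound_ligand_quadratic(1, 1e-6, 5e-8), 1e-12)
  # frozen oracle value: K=1e-7, X=2e-7, FL=5e-8
  b <- bound_ligand_quadratic(1e-7, 2e-7, 5e-8)
  expect_equal(b, 3.13859e-8, tolerance = 1e-4)
  expect_equal(b, oracle_bound_1to1(1e-7, 2e-7, 5e-8), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    K <- 10^stats::runif(1, -10, -3)
    X <- 10^stats::runif(1, -9, -3)
    FL <- 10^stats::runif(1, -9, -6)
    expect_equal(bound_ligand_quadratic(K, X, FL),
                 oracle_bound_1to1(K, X, FL), tolerance = 1e-9)
  }
})

test_that("quadratic is monotone in X and K, and bounded", {
  set.seed(7)
  for (i in 1:25) {
    FL <- 10^stats::runif(1, -9, -6)
    K <- 10^stats::runif(1, -9, -4)
    X <- sort(10^stats::runif(20, -10, -3))
    b <- bound_ligand_quadratic(K, X, FL)
    expect_true(all(diff(b) >= -1e-18))
    expect_true(all(b >= 0 & b <= pmin(X, FL) + 1e-18))
    b_tighter <- bound_ligand_quadratic(K / 10, X, FL)
    expect_true(all(b_tighter >= b - 1e-18))
  }
})

test_that("fraction bound: midpoint, zero, and depletion at X = K", {
  K <- 1e-6
  # dilute tracer: hyperbola midpoint at X = K
  expect_equal(fraction_bound_curve(K, 1e-12, K), 0.5, tolerance = 1e-5)
  expect_equal(fraction_bound_curve(K, 1e-12, 0), 0)
  # tracer depletion: at X = K with FL comparable to K the free protein
  # is depleted, so occupancy falls below the dilute-limit 0.5
  fb <- fraction_bound_curve(98.8e-9, 50e-9, 98.8e-9)
  expect_equal(fb, oracle_bound_1to1(98.8e-9, 98.8e-9, 50e-9) / 50e-9,
               tolerance = 1e-9)
  expect_lt(fb, 0.5)
})

test_that("mass-action solver reduces to the quadratic in both limits", {
  # all-dimer limit: two independent grooves = site pool of monomer_total
  mech <- coupled_mechanism(Kdim = 1e-20, Kd_site = 98.8e-9, valency = 1)
  s <- solve_mass_action(mech, list(monomer_total = 2e-7, peptide_total = 5e-8),
                         tol = 1e-12)
  expect_equal(s$peptide_bound, bound_ligand_quadratic(98.8e-9, 2e-7, 5e-8),
               tolerance = 1e-9)
  # all-monomer limit
  mech2 <- coupled_mechanism(Kdim = 1e3, Kd_site = 1e-6, valency = 1)
  s2 <- solve_mass_action(mech2, list(monomer_total = 1e-5, peptide_total = 1e-7),
                          tol = 1e-12)
  expect_equal(s2$peptide_bound, bound_ligand_quadratic(1e-6, 1e-5, 1e-7),
               tolerance = 1e-9)
})

test_that("mass-action solver: dimerization law, conservation, bridging", {
  # peptide-free partition obeys Kdim = [M]^2/[D]
  s <- solve_mass_action(coupled_mechanism(1e-6, 1e-7),
                         list(monomer_total = 1e-6, peptide_total = 0))
  expect_equal(s$M^2 / s$D, 1e-6, tolerance = 1e-8)

  # conservation residuals hold across a random sweep
  set.seed(11)
  for (i in 1:20) {
    mech <- coupled_mechanism(Kdim = 10^stats::runif(1, -9, -5),
                              Kd_site = 10^stats::runif(1, -8, -5),
                              alpha_bridge = 10^stats::runif(1, -5, -2),
                              valency = 2)
    Pt <- 10^stats::runif(1, -7, -4); Lt <- 10^stats::runif(1, -8, -5)
    s <- solve_mass_action(mech, list(monomer_total = Pt, peptide_total = Lt))
    mono <- s$M + 2 * s$D + s$ML + 2 * (s$DL + s$DL2 + s$Dbr)
    pep <- s$L + s$ML + s$DL + 2 * s$DL2 + s$Dbr
    expect_equal(mono, Pt, tolerance = 1e-9)
    expect_equal(pep, Lt, tolerance = 1e-9)
  }

  # strong effective molarity: nearly all bound peptide is bridged
  mech3 <- coupled_mechanism(Kdim = 1e-12, Kd_site = 1e-6,
                             alpha_bridge = 1e-1, valency = 2)
  s3 <- solve_mass_action(mech3, list(monomer_total = 1e-5,
                                      peptide_total = 1e-8))
  expect_gt(s3$Dbr / s3$peptide_bound, 0.999)
})

test_that("Langmuir closed forms match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  kon <- 1.51e6; koff <- 0.0048; Rmax <- 100
  Kd <- koff / kon
  C <- 10 * Kd
  kobs <- kon * C + koff
  t_end <- 5 * log(2) / kobs
  times <- seq(0, t_end, length.out = 60)
  ode <- deSolve::ode(y = c(R = 0), times = times,
                      func = function(t, y, p) {
                        list(kon * C * (Rmax - y[1]) - koff * y[1])
                      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  closed <- langmuir_association(times, kon, koff, Rmax, C)
  expect_equal(unname(ode[, "R"][-1]), closed[-1], tolerance = 1e-6)

  # t = 0 and steady state
  expect_equal(langmuir_association(0, kon, koff, Rmax, C), 0)
  expect_equal(langmuir_association(1e6, kon, koff, Rmax, C),
               Rmax * C / (C + Kd), tolerance = 1e-12)
  # 99% of Req at t = ln(100)/kobs
  expect_equal(langmuir_association(log(100) / kobs, kon, koff, Rmax, C),
               0.99 * Rmax * C / (C + Kd), tolerance = 1e-9)
})

test_that("dissociation decay: start, half-life, 1% point", {
  expect_equal(langmuir_dissociation(0, 0.1208, 50), 50)
  expect_equal(langmuir_dissociation(log(2) / 0.1208, 0.1208, 50), 25)
  # ln(100)/0.1208 = 38.1 s, so below 1% of R0 within 39 s
  expect_lt(langmuir_dissociation(39, 0.1208, 50), 0.01 * 50)
  expect_gt(langmuir_dissociation(38, 0.1208, 50), 0.01 * 50)
})

test_that("steady-state hyperbola algebra", {
  expect_equal(steady_state_response(1e-6, 1e-6, 80), 40)
  expect_equal(steady_state_response(0, 1e-6, 80), 0)
  expect_equal(steady_state_response(9e-6, 1e-6, 80), 72)
})

test_that("Gibbs energies reproduce calorimetric table values", {
  expect_equal(delta_g(1), 0)
  expect_equal(delta_g(870e-9), -34.6, tolerance = 0.01)
  expect_equal(delta_g(21e-6), -26.7, tolerance = 0.01)
  # strictly increasing in Kd
  kds <- 10^seq(-9, -3, by = 0.5)
  expect_true(all(diff(delta_g(kds)) > 0))
  expect_error(delta_g(0), "positive")
  # decomposition identity: -TdS + dH recovers dG exactly
  dG <- delta_g(870e-9); dH <- -16.1
  expect_identical(entropic_term(dG, dH) + dH, dG)
  expect_equal(entropic_term(-34.6, -16.1), -18.5)
  expect_equal(entropic_term(-26.7, -21.4), -5.3)
  expect_equal(entropic_term(-10, -10), 0)
})
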