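default_exp <- function(Kd = 870e-9, dH = -16.1, n = 1,
                        cell_conc = 100e-6, syringe_conc = 1e-3,
                        injections = rep(2e-6, 20)) {
  ex <- itc_experiment(cell_volume = 200e-6, cell_conc = cell_conc,
                       syringe_conc = syringe_conc,
                       injection_volumes = injections)
  ex$heats <- itc_forward(list(Kd = Kd, dH = dH, n = n), ex)
  ex
}

test_that("forward model: zero enthalpy, conservation, oracle per injection", {
  ex <- default_exp(dH = 0)
  expect_true(all(ex$heats == 0))

  # cumulative heat approaches n dH V0 [P]0 for a saturating schedule
  ex2 <- default_exp(Kd = 1e-8, dH = -20, cell_conc = 20e-6,
                     syringe_conc = 400e-6)
  expect_equal(sum(ex2$heats) * 1e-6, -20e3 * 200e-6 * 20e-6,
               tolerance = 0.01)

  # per-injection bound concentrations agree with the brute-force oracle
  ex3 <- default_exp(Kd = 5e-7, dH = -15, n = 0.8)
  cc <- phosphofit:::.itc_cell_conc(ex3)
  q_oracle <- numeric(length(ex3$injection_volumes))
  B_prev <- 0
  for (i in seq_along(q_oracle)) {
    B <- oracle_bound_1to1(5e-7, 0.8 * cc$P[i], cc$L[i])
    dV <- ex3$injection_volumes[i]
    q_oracle[i] <- -15e3 * (200e-6 * (B - B_prev) + dV * (B + B_prev) / 2)
    B_prev <- B
  }
  expect_equal(ex3$heats, q_oracle / 1e-6, tolerance = 1e-8)
})

test_that("forward model is invariant to splitting an injection", {
  ex <- default_exp()
  vols <- ex$injection_volumes
  split_vols <- c(vols[1:4], rep(vols[5] / 2, 2), vols[6:20])
  ex_split <- itc_experiment(cell_volume = 200e-6, cell_conc = 100e-6,
                             syringe_conc = 1e-3,
                             injection_volumes = split_vols)
  q_split <- itc_forward(list(Kd = 870e-9, dH = -16.1, n = 1), ex_split)
  expect_equal(sum(q_split), sum(ex$heats), tolerance = 5e-3)
})

test_that("c-value controls isotherm shape: shallow at 1, step at 500", {
  slope_at_n <- function(Kd) {
    ex <- default_exp(Kd = Kd, dH = -20, cell_conc = 20e-6,
                      syringe_conc = 400e-6,
                      injections = rep(1e-6, 40))
    ratio <- phosphofit:::.itc_molar_ratio(ex)
    # normalized heat per mole injected around the equivalence point
    qn <- ex$heats / diff(c(0, ratio))
    mid <- which.min(abs(ratio - 1))
    abs(qn[mid + 1] - qn[mid - 1]) / (ratio[mid + 1] - ratio[mid - 1])
  }
  expect_gt(slope_at_n(20e-6 / 500), 10 * slope_at_n(20e-6 / 1))
})

test_that("noiseless fit recovers Kd, dH and n; derived energies consistent", {
  ex <- default_exp()
  fit <- fit_itc(ex)
  expect_equal(fit$Kd, 870e-9, tolerance = 5e-3)
  expect_equal(fit$dH, -16.1, tolerance = 5e-3)
  expect_equal(fit$n, 1, tolerance = 5e-3)
  expect_equal(fit$dG, delta_g(fit$Kd), tolerance = 1e-12)
  # decomposition is an exact identity of the fit
  expect_equal(fit$dG, fit$dH + fit$minus_TdS, tolerance = 1e-12)
  expect_equal(fit$dG, -34.6, tolerance = 0.05)
  expect_equal(fit$minus_TdS, -18.5, tolerance = 0.05)
})

test_that("fitted dH is scale-equivariant; Kd and n are not", {
  ex <- default_exp()
  ex2 <- ex
  ex2$heats <- ex$heats * 2
  f1 <- fit_itc(ex)
  f2 <- fit_itc(ex2)
  expect_equal(f2$dH, 2 * f1$dH, tolerance = 1e-6)
  expect_equal(f2$Kd, f1$Kd, tolerance = 1e-6)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
})

test_that("first-injection discard and c-value warning", {
  ex <- default_exp(injections = rep(2e-6, 21))
  ex$heats[1] <- ex$heats[1] * 0.4  # anomalous first injection
  f_all <- fit_itc(ex)
  f_disc <- fit_itc(ex, discard_first = TRUE)
  expect_equal(f_disc$Kd, 870e-9, tolerance = 5e-3)
  expect_gt(abs(f_all$Kd - 870e-9), abs(f_disc$Kd - 870e-9))

  # very weak binding: c-value below 1 triggers a reliability warning
  ex_weak <- default_exp(Kd = 5e-3, dH = -20, cell_conc = 20e-6,
                         syringe_conc = 2e-3)
  expect_warning(fit_itc(ex_weak), class = "phosphofit_c_value_warning")
})

test_that("noisy recovery stays inside the reported uncertainty scale", {
  # tandem-peptide conditions with 2% heat noise
  errs <- vapply(1:25, function(i) {
    d <- itc_design(true_Kd = 14e-9, true_dH = -22.1, cell_conc = 20e-6,
                    syringe_conc = 200e-6, heat_noise_sd = 0.02, seed = i)
    ex <- gen_itc(d)
    f <- suppressWarnings(fit_itc(ex))
    (f$Kd - 14e-9) / 14e-9
  }, numeric(1))
  # the published value carries a +/-10/14 relative uncertainty band
  expect_lt(abs(mean(errs)), 10 / 14)
})
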