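make_plate <- function(S, P, conc = 10^seq(-8, -5, length.out = length(S)),
                       rep = 1L) {
  data.frame(concentration_M = conc, replicate = rep, S = S, P = P)
}

test_that("anisotropy arithmetic from the two channels", {
  # S = P with G = 1: unpolarized, r = 0
  cv <- compute_anisotropy(make_plate(rep(2, 6), rep(2, 6)), 50e-9)
  expect_equal(cv$r_mean, rep(0, 6))
  # P = 0: fully polarized, r = 1
  cv <- compute_anisotropy(make_plate(rep(2, 6), rep(0, 6)), 50e-9)
  expect_equal(cv$r_mean, rep(1, 6))
  # direct arithmetic: S=3, P=1, G=1 -> I=5, r=0.4
  cv <- compute_anisotropy(make_plate(rep(3, 6), rep(1, 6)), 50e-9)
  expect_equal(cv$r_mean, rep(0.4, 6))
  # non-positive total intensity is a data-quality error naming the well
  expect_error(
    compute_anisotropy(make_plate(c(rep(3, 5), -3), c(rep(1, 5), 0)), 50e-9),
    class = "phosphofit_data_quality_error")
})

test_that("pipeline is equivariant under a common channel gain", {
  d <- fa_design(noise_sd = 0.01, top_conc = 10e-6, seed = 3)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 98.8e-9))
  p_gain <- transform(p, S = S * 7.3, P = P * 7.3)
  f1 <- fa_fit(p, d$tracer_conc)
  f2 <- fa_fit(p_gain, d$tracer_conc)
  expect_equal(f1$Kd, f2$Kd, tolerance = 1e-8)
})

test_that("duplicating replicate rows leaves the estimate unchanged", {
  d <- fa_design(noise_sd = 0.01, top_conc = 10e-6, seed = 9)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 98.8e-9))
  f1 <- fa_fit(p, d$tracer_conc)
  f2 <- fa_fit(rbind(p, p), d$tracer_conc)
  expect_equal(f1$Kd, f2$Kd, tolerance = 1e-10)
})

test_that("logistic window recovers generator plateaus on clean data", {
  d <- fa_design(noise_sd = 0, top_conc = 10e-6)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 98.8e-9))
  cv <- compute_anisotropy(p, d$tracer_conc)
  lf <- fit_logistic(cv)
  expect_equal(lf$rmin, d$r_free, tolerance = 5e-3)
  expect_equal(lf$rmax, d$r_bound_event1, tolerance = 5e-3)
  expect_gt(lf$rmax, lf$rmin)
})

test_that("fraction-bound conversion is the linear rescale at lambda 1", {
  d <- fa_design(noise_sd = 0, top_conc = 10e-6)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 98.8e-9))
  cv <- compute_anisotropy(p, d$tracer_conc)
  lf <- fit_logistic(cv)
  fb <- to_fraction_bound(cv, lf)
  expect_true(all(fb >= 0 & fb <= 1))
  manual <- pmin(pmax((cv$r_mean - lf$rmin) / (lf$rmax - lf$rmin), 0), 1)
  expect_equal(as.numeric(fb), manual)
  # r at the plateaus maps to 0 and 1
  cv$r_mean[1] <- lf$rmin
  cv$r_mean[length(cv$r_mean)] <- lf$rmax
  fb2 <- to_fraction_bound(cv, lf)
  expect_equal(fb2[1], 0)
  expect_equal(fb2[length(fb2)], 1)
})

test_that("truncated titrations signal a lower-bound-only outcome", {
  # midpoint never crossed
  d <- fa_design(noise_sd = 0, top_conc = 1e-6, n_points = 12)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 31.6e-6))
  cv <- compute_anisotropy(p, d$tracer_conc)
  expect_error(fit_logistic(cv), class = "phosphofit_saturation_error")

  # the weak-binder scenario: Kd = 31.6 uM sampled only to 100 uM at 1%
  # noise reaches ~76% of its window; only a bound can be reported
  d2 <- fa_design(noise_sd = 0.01, top_conc = 100e-6, seed = 21)
  p2 <- gen_fa_titration(d2, list(type = "single_site", Kd = 31.6e-6))
  fit <- fa_fit(p2, d2$tracer_conc)
  expect_true(is.na(fit$Kd))
  expect_equal(fit$lower_bound, 100e-6)
})

test_that("tracer-depleted regime: quadratic unbiased, hyperbola biased", {
  # Kd below the 50 nM tracer concentration
  d <- fa_design(noise_sd = 0, top_conc = 2e-6)
  p <- gen_fa_titration(d, list(type = "single_site", Kd = 5e-9))
  fit <- fa_fit(p, d$tracer_conc)
  expect_equal(fit$Kd, 5e-9, tolerance = 5e-3)
  # naive hyperbola fitted to the same fraction-bound data overestimates
  cv <- compute_anisotropy(p, d$tracer_conc)
  lf <- fit_logistic(cv)
  fb <- as.numeric(to_fraction_bound(cv, lf))
  hyp <- minpack.lm::nlsLM(fb ~ conc / (10^logK + conc),
                           start = list(logK = -8),
                           data = list(fb = fb, conc = cv$concentration))
  Kd_hyp <- 10^coef(hyp)[[1]]
  expect_gt(Kd_hyp / 5e-9, 3)  # grossly biased high
})

test_that("biphasic decomposition: round trip, split override, fallback", {
  d <- fa_design(noise_sd = 0, top_conc = 500e-6)
  p <- gen_fa_titration(d, list(type = "two_event",
                                Kd1 = 30e-9, Kd2 = 10.7e-6))
  cv <- compute_anisotropy(p, d$tracer_conc)
  bf <- fit_biphasic(cv)
  expect_s3_class(bf, "biphasic_fit")
  expect_lt(bf$Kd1, bf$Kd2)
  expect_equal(bf$Kd1, 30e-9, tolerance = 0.01)
  expect_equal(bf$Kd2, 10.7e-6, tolerance = 0.01)
  # the split lies between the two midpoints
  expect_gt(bf$split_conc, 30e-9)
  expect_lt(bf$split_conc, 10.7e-6)

  # manual split gives the same answer after polishing
  bf2 <- fit_biphasic(cv, split = 1e-6)
  expect_equal(bf2$Kd1, bf$Kd1, tolerance = 1e-6)

  # a single-event curve falls back with a classed warning
  p1 <- gen_fa_titration(fa_design(noise_sd = 0, top_conc = 10e-6),
                         list(type = "single_site", Kd = 98.8e-9))
  cv1 <- compute_anisotropy(p1, 50e-9)
  expect_warning(sf <- fit_biphasic(cv1),
                 class = "phosphofit_single_event_warning")
  expect_s3_class(sf, "single_site_fit")
  expect_equal(sf$Kd, 98.8e-9, tolerance = 0.05)
})
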