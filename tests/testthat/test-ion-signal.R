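test_that("oscillation bookkeeping: defaults, period, wavenumber, positivity", {
  osc <- oscillation_params()
  expect_equal(oscillation_period(osc), 2 * pi / 3.77)
  expect_equal(oscillation_wavenumber(osc), 20.0143, tolerance = 1e-4)
  expect_error(oscillation_params(a_parent = 0.1, b_parent = 0.2), "exceed")
})

test_that("probe convolution preserves constants and reproduces the smoothed step", {
  sig_ps <- (70 / (2 * sqrt(2 * log(2)))) / 1000
  t <- seq(-2, 2, by = 0.001)

  ## constant input is unchanged
  cv <- convolve_probe(make_trace(t, rep(0.42, length(t))), probe_fwhm = 70)
  expect_lt(max(abs(cv$rho - 0.42)), 1e-12)

  ## symmetric step (knot value 0.5 at t = 0) gives exactly 0.5 at t = 0
  y <- ifelse(t < 0, 0, ifelse(t > 0, 1, 0.5))
  cv <- convolve_probe(make_trace(t, y), probe_fwhm = 70, at = 0)
  expect_equal(cv$rho[1L], 0.5, tolerance = 1e-12, ignore_attr = TRUE)

  ## step response matches the analytic ramp-smoothed erf form
  y <- as.numeric(t >= 0)
  at <- seq(-0.3, 0.3, by = 0.003)
  cv <- convolve_probe(make_trace(t, y), probe_fwhm = 70, at = at)
  expect_lt(max(abs(cv$rho[, 1L] - ramp_step_conv(at, -0.001, sig_ps))), 1e-6)

  ## coarse grids are refused
  expect_error(convolve_probe(make_trace(seq(-2, 2, by = 0.05),
                                         rep(1, 81)), probe_fwhm = 70),
               "too coarse")
})

test_that("ion-yield model composes channels as specified", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(), t_end = 20)
  cv <- convolve_probe(tr, at = seq(-1, 18, by = 0.05))
  osc <- oscillation_params()
  delays <- seq(-0.5, 15, by = 0.25)

  ## only C nonzero: water tracks rho55, others vanish
  m <- model_ion_yields(cv, signal_coefficients(A = c(0, 0, 0),
                                                B = c(0, 0, 0, 0), C = 2),
                        osc, delays)
  expect_true(all(m$parent$yield == 0))
  expect_true(all(m$fragment$yield == 0))
  r55 <- approx(cv$t, cv$rho[, "rho55"], delays)$y
  expect_equal(m$water$yield, 2 * r55, tolerance = 1e-12)

  ## b = 0 removes the modulation
  osc0 <- oscillation_params(b_parent = 0, b_fragment = 0)
  cf <- signal_coefficients()
  m0 <- model_ion_yields(cv, cf, osc0, delays)
  r <- sapply(c("rho22", "rho33", "rho44"), function(cl)
    approx(cv$t, cv$rho[, cl], delays)$y)
  expect_equal(m0$parent$yield,
               osc0$a_parent * as.numeric(r %*% cf$A), tolerance = 1e-12)

  ## linearity in the coefficients (gauge property of one channel)
  m1 <- model_ion_yields(cv, signal_coefficients(C = 1), osc, delays)
  m7 <- model_ion_yields(cv, signal_coefficients(C = 7), osc, delays)
  expect_equal(m7$water$yield, 7 * m1$water$yield, tolerance = 1e-12)

  expect_error(model_ion_yields(cv, cf, osc, c(-3, 0, 1)), "outside")
})

test_that("fragment channel rises monotonically for ordered coefficients without modulation", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(rabi_omega0 = 0.3),
                        t_end = 130)
  delays <- seq(1.5, 129, by = 0.5)        # post-pulse region
  cv <- convolve_probe(tr, at = seq(1, 129.5, by = 0.05))
  m <- model_ion_yields(cv, signal_coefficients(B = c(0.1, 0.3, 0.6, 1.0)),
                        oscillation_params(b_parent = 0, b_fragment = 0),
                        delays)
  expect_true(all(diff(m$fragment$yield) >= -1e-10))
})

test_that("oscillation fit recovers exact parameters and resists noise", {
  t <- seq(100, 133.4, by = 0.0417)        # high-resolution window
  truth <- list(a = 0.92, b = 0.11, omega = 3.77, phi = 1.77)
  y0 <- truth$a + truth$b * cos(truth$omega * t + truth$phi)
  fit <- fit_oscillation(ion_yield_curve(t, y0, rep(1, length(t)), "fragment"))
  expect_equal(fit$a, truth$a, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
  expect_equal(fit$omega, truth$omega, tolerance = 1e-6)
  expect_equal(fit$phi, truth$phi, tolerance = 1e-6)

  ## 2% noise, 20 periods: omega within 0.5% over 20 seeded replicates
  t2 <- seq(0, 20 * 2 * pi / 3.77, by = 0.1)
  omegas <- vapply(1:20, function(s) {
    set.seed(s)
    y <- y0n <- truth$a + truth$b * cos(truth$omega * t2 + truth$phi)
    y <- y + rnorm(length(t2), 0, 0.02 * mean(y0n))
    fit_oscillation(ion_yield_curve(t2, y, rep(1, length(t2)), "x"))$omega
  }, 0)
  expect_true(all(abs(omegas - truth$omega) / truth$omega < 0.005))

  ## an undamped cosine leaves residuals at the noise level (no damping term)
  set.seed(11)
  noise_sd <- 0.02 * truth$a
  y <- truth$a + truth$b * cos(truth$omega * t + truth$phi) +
    rnorm(length(t), 0, noise_sd)
  f <- fit_oscillation(ion_yield_curve(t, y, rep(1, length(t)), "fragment"))
  expect_lt(sqrt(f$rss / length(t)), 1.2 * noise_sd)

  ## undersampled scans are refused
  tu <- seq(0, 50, by = 1.2)               # < 4 points per 1.67 ps period
  yu <- truth$a + truth$b * cos(truth$omega * tu + truth$phi)
  expect_error(fit_oscillation(ion_yield_curve(tu, yu, rep(1, length(tu)),
                                               "x"), omega_init = 3.77),
               "ndersampled")
})
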