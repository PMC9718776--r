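test_that("TKER transform is the momentum-conservation mass scaling", {
  expect_identical(ke_to_tker(0), 0)
  expect_equal(ke_to_tker(100, 18.015, 135.166), 115.3776, tolerance = 1e-4)
  ## linearity
  e <- c(5, 40, 250)
  expect_equal(ke_to_tker(3 * e), 3 * ke_to_tker(e), tolerance = 1e-12)
  expect_error(ke_to_tker(1, 20, 18), "exceed")
  expect_error(ke_to_tker(1, -2, 18), "positive")

  sp <- ke_spectrum(seq(0, 100, 10), rep(1, 10), delay = 70)
  tk <- spectrum_to_tker(sp)
  expect_equal(tk$bin_edges, sp$bin_edges * 135.166 / (135.166 - 18.015))
  expect_identical(tk$counts, sp$counts)
  expect_identical(spectrum_to_tker(tk), tk)   # idempotent
})

test_that("negative-delay background subtraction behaves and round-trips", {
  edges <- seq(0, 200, 10)
  mk <- function(counts, delay) ke_spectrum(edges, counts, delay)
  a <- mk(rpois(20, 50), -10)

  ## a single negative-delay spectrum subtracted from itself is zero
  out <- subtract_negative_delay_background(list(a))
  expect_true(all(out$spectra[[1L]]$counts == 0))
  expect_identical(out$background$counts, as.numeric(a$counts))

  ## the background of two identical spectra equals either one
  out2 <- subtract_negative_delay_background(list(a, mk(a$counts, -5)))
  expect_identical(out2$background$counts, as.numeric(a$counts))

  ## round-trip: subtracting then re-adding the background is exact
  set.seed(2)
  spectra <- list(mk(rpois(20, 40), -8), mk(rpois(20, 40), -4),
                  mk(rpois(20, 80), 70), mk(rpois(20, 90), 100))
  sub <- subtract_negative_delay_background(spectra)
  for (i in seq_along(spectra))
    expect_identical(sub$spectra[[i]]$counts + sub$background$counts,
                     as.numeric(spectra[[i]]$counts))

  ## a static + dynamic construction leaves the dynamic part
  static <- 200 * dgamma((edges[-1] + edges[-21]) / 2, 1.5, scale = 60)
  dynamic <- 150 * dgamma((edges[-1] + edges[-21]) / 2, 1.5, scale = 30)
  sub2 <- subtract_negative_delay_background(
    list(mk(static, -5), mk(static + dynamic, 80)))
  expect_equal(sub2$spectra[[2L]]$counts, dynamic, tolerance = 1e-12)

  expect_error(subtract_negative_delay_background(
    list(mk(rep(1, 20), 5))), "negative-delay")
  expect_error(subtract_negative_delay_background(
    list(a, ke_spectrum(seq(0, 100, 5), rep(1, 20), -3))), "binning")
})

test_that("Maxwell-Boltzmann fits recover kT and report the analytic mean", {
  edges <- seq(0, 500, 5)
  mid <- (edges[-1] + edges[-length(edges)]) / 2

  ## exact histogram of the 3D form: kT to 0.1%, mean = (3/2) kT
  y <- sqrt(mid) * exp(-mid / 50)
  f <- fit_maxwell_boltzmann(ke_spectrum(edges, y, 70))
  expect_equal(f$kT, 50, tolerance = 1e-3)
  expect_identical(f$mean, 1.5 * f$kT)

  ## exact projected form: mean = kT
  y2 <- exp(-mid / 80)
  f2 <- fit_maxwell_boltzmann(ke_spectrum(edges, y2, 70), form = "projected")
  expect_equal(f2$kT, 80, tolerance = 1e-3)
  expect_identical(f2$mean, f2$kT)

  ## sampled: 1e5 draws at kT = 30, mean recovered within 2% over 20 seeds
  means <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rmaxboltz(1e5, 30)
    x <- x[x <= 500]
    cts <- hist(x, breaks = edges, plot = FALSE)$counts
    fit_maxwell_boltzmann(ke_spectrum(edges, cts, 70))$mean
  }, 0)
  expect_true(all(abs(means - 45) / 45 < 0.02))
  ## consistency: the mean of the estimates is closer than single draws
  expect_lt(abs(mean(means) - 45) / 45, 0.01)

  expect_error(fit_maxwell_boltzmann(ke_spectrum(edges, -y, 70)),
               "insufficient")
})

test_that("ion-dipole potential follows the inverse-square charge-dipole law", {
  expect_equal(ion_dipole_potential(500, 90), 0, tolerance = 1e-15)
  expect_equal(ion_dipole_potential(980, 38), ion_dipole_potential(490, 38) / 4,
               tolerance = 1e-12)
  ## published geometry: about 0.19 eV
  expect_equal(ion_dipole_potential(490, 38, mu = 1.96, q = 1), 0.19285,
               tolerance = 1e-4)
  expect_error(ion_dipole_potential(-1, 0), "positive")
})

test_that("TKER evolution is monotone with the published asymptote", {
  m <- ion_dipole_model()
  t <- seq(51, 500, by = 1)
  tk <- tker_evolution(m, t)
  expect_true(all(diff(tk) <= 0))
  expect_true(all(tk >= m$E_pump - m$E_a))
  ## asymptotic TKER: 4.61 - 4.57 = 0.04 eV, below 50 meV
  expect_equal(tker_evolution(m, 1e5), 0.04, tolerance = 1e-5)
  expect_lt(tker_evolution(m, 1e5), 0.050)
  ## value at t_d combines the asymptote with the contact potential
  expect_equal(tker_evolution(m, m$t_d), 0.04 + 0.19285, tolerance = 1e-4)
  ## v = 0 freezes the separation
  m0 <- ion_dipole_model(v = 0)
  expect_equal(tker_evolution(m0, c(60, 200)),
               rep(0.04 + 0.19285, 2), tolerance = 1e-4)
  expect_error(tker_evolution(m, 30), "undefined")
  expect_identical(tker_evolution(m, c(30, 60), mask_before_td = TRUE)[1L],
                   NA_real_)
})

test_that("ion-dipole fits recover the generating model", {
  ## noiseless: all five parameters exact from a true-model start
  s0 <- generate_mean_tker(default_truth, rel_noise = 0, seed = 1)
  f0 <- fit_ion_dipole(s0)
  expect_equal(unname(coef(f0)), c(490, 12, 51, 38, 4.57), tolerance = 1e-3)
  expect_lt(max(abs(residuals(f0))), 1e-9)
  ## the identifiable combination V(R_eq, theta) is pinned even though
  ## (R_eq, t_d) are individually degenerate
  expect_equal(ion_dipole_potential(f0$estimate["R_eq_pm"],
                                    f0$estimate["theta_deg"]),
               ion_dipole_potential(490, 38), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(fit_ion_dipole(s0[1:5, ]), "at least 8")
})

test_that("the spectra pipeline recovers v and E_a end to end", {
  spectra <- generate_ke_spectra(default_truth, seed = 5)
  series <- mean_tker_series(spectra)
  fit <- fit_ion_dipole(series)
  expect_equal(unname(fit$estimate["v_mps"]), 12, tolerance = 0.2)
  expect_equal(unname(fit$estimate["E_a_eV"]), 4.57, tolerance = 0.005)
})
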