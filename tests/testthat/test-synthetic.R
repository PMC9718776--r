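test_that("the published scan design is reproduced", {
  d <- paper_scan_design()
  expect_equal(d$parent[1:2], c(-1.535, -1.118))
  expect_true(any(abs(d$parent - 6.805) < 1e-9))    # end of the fine block
  expect_true(any(abs(d$parent - 7.639) < 1e-9))    # the single 834 fs step
  steps <- diff(d$parent)
  expect_equal(sort(unique(round(steps, 3))), c(0.417, 0.834, 1.668))
  expect_equal(d$water[1], -5.705)
  expect_equal(unique(round(diff(d$water), 3)), 4.17)
  expect_equal(max(d$water), 140.245)
  expect_error(scan_design(c(1, 0.5)), "increasing")
})

test_that("scan generation is deterministic and noiseless equals the model", {
  d <- paper_scan_design()
  s1 <- generate_ion_yield_scan(default_truth, d, seed = 3)
  s2 <- generate_ion_yield_scan(default_truth, d, seed = 3)
  expect_identical(s1, s2)
  s3 <- generate_ion_yield_scan(default_truth, d, seed = 4)
  expect_false(identical(s1$parent$yield, s3$parent$yield))
  ## different seeds share the same underlying model
  s0a <- generate_ion_yield_scan(default_truth, d, seed = 3, noiseless = TRUE)
  s0b <- generate_ion_yield_scan(default_truth, d, seed = 4, noiseless = TRUE)
  expect_identical(s0a$parent$yield, s0b$parent$yield)
  ## provenance travels with the data
  expect_identical(attr(s1, "seed"), 3)
  expect_s3_class(attr(s1, "truth"), "ground_truth")
  ## Poisson mode attaches counting uncertainties
  sp <- generate_ion_yield_scan(default_truth,
                                paper_scan_design(noise_model = "poisson"),
                                seed = 3)
  expect_true(all(sp$water$sigma > 0))
})

test_that("the fragment fast rise lags the parent fast rise", {
  fine <- scan_design(seq(-2, 4, by = 0.02))
  s <- generate_ion_yield_scan(default_truth, fine, seed = 1,
                               noiseless = TRUE)
  ## remove the oscillation-free baseline and compare derivative peaks
  dp <- diff(s$parent$yield)
  df <- diff(s$fragment$yield)
  t_mid <- s$parent$delay_ps[-1]
  expect_gt(t_mid[which.max(df)], t_mid[which.max(dp)])
})

test_that("generated spectra have exchangeable negative-delay replicates", {
  spectra <- generate_ke_spectra(default_truth, seed = 8)
  delays <- vapply(spectra, `[[`, 0, "delay")
  neg <- which(delays < 0)
  expect_gte(length(neg), 2L)
  a <- spectra[[neg[1L]]]$counts
  b <- spectra[[neg[2L]]]$counts
  keep <- (a + b) >= 10
  p <- suppressWarnings(chisq.test(rbind(a[keep], b[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("zero dynamic amplitude leaves positive delays identical to background", {
  spectra <- generate_ke_spectra(default_truth, delays = c(-10, -6, 100),
                                 dyn_fraction = 0, seed = 2)
  a <- spectra[[1L]]$counts
  c3 <- spectra[[3L]]$counts
  keep <- (a + c3) >= 10
  p <- suppressWarnings(chisq.test(rbind(a[keep], c3[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("the dynamic TKER component cools between 66 and 138 ps", {
  spectra <- generate_ke_spectra(default_truth, delays = c(-10, -6, 66, 138),
                                 samples_per_delay = 50000, seed = 6)
  series <- mean_tker_series(spectra, min_delay = 60)
  m66 <- series$mean_tker_meV[series$delay_ps == 66]
  m138 <- series$mean_tker_meV[series$delay_ps == 138]
  expect_lt(m138, m66)
  ## and the noiseless means follow the ion-dipole curve
  expect_equal(m66, 1000 * tker_evolution(default_truth$dipole, 66),
               tolerance = 0.05)
})

test_that("mean-TKER generation is seeded and unbiased", {
  s1 <- generate_mean_tker(default_truth, seed = 9)
  s2 <- generate_mean_tker(default_truth, seed = 9)
  expect_identical(s1, s2)
  s0 <- generate_mean_tker(default_truth, rel_noise = 0, seed = 1)
  expect_equal(s0$mean_tker_meV,
               1000 * tker_evolution(default_truth$dipole, s0$delay_ps),
               tolerance = 1e-12)
  expect_warning(generate_ke_spectra(default_truth, delays = c(60, 80),
                                     samples_per_delay = 100, seed = 1),
                 "negative")
})
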