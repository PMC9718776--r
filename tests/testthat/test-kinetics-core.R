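test_that("level scheme derives rates from lifetimes and validates input", {
  s <- level_scheme(tau2 = 445, tau3 = 13, tau4 = 96)
  expect_identical(s$gamma22, 1 / 0.445)
  expect_identical(s$gamma33, 1 / 13)
  expect_identical(s$gamma44, 1 / 96)
  expect_identical(s$gamma21, s$gamma22 / 2)   # default coherence decay
  expect_identical(s$delta_omega, 0)
  expect_error(level_scheme(tau2 = -1), "positive")
  expect_error(level_scheme(tau3 = 0), "positive")
})

test_that("IRF envelope is peak-normalized, even, and vanishing", {
  p <- excitation_pulse()
  expect_identical(irf_envelope(0, p), 1)
  t <- c(0.1, 0.7, 2)
  expect_equal(irf_envelope(t, p), irf_envelope(-t, p))
  expect_lt(irf_envelope(5, p), 1e-6)
  expect_error(excitation_pulse(rabi_omega0 = -1), "non-negative")
})

test_that("populations are conserved and bounded along the integration", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(), t_end = 30)
  expect_lt(max(abs(rowSums(tr$rho) - 1)), 1e-8)
  expect_true(all(tr$rho > -1e-8 & tr$rho < 1 + 1e-8))
  ## ground state only depletes, product only accumulates
  expect_true(all(diff(tr$rho[, "rho11"]) <= 1e-12))
  expect_true(all(diff(tr$rho[, "rho55"]) >= -1e-12))
})

test_that("with no coupling all population stays in the ground state", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(rabi_omega0 = 0),
                        t_end = 10)
  expect_lt(max(abs(tr$rho[, "rho11"] - 1)), 1e-12)
  expect_lt(max(abs(tr$rho[, -1])), 1e-12)
})

test_that("weak-field excited fraction scales quadratically in the Rabi frequency", {
  sch <- level_scheme()
  f <- function(om) {
    tr <- integrate_bloch(sch, excitation_pulse(rabi_omega0 = om), t_end = 5)
    1 - unname(tr$rho[nrow(tr$rho), "rho11"])
  }
  ratio <- f(0.05) / f(0.025)
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("fixed pulse area gives the same excited fraction in the weak field", {
  sch <- level_scheme()
  f <- function(om, tirf) {
    tr <- integrate_bloch(sch, excitation_pulse(rabi_omega0 = om,
                                                tau_irf = tirf), t_end = 5)
    1 - unname(tr$rho[nrow(tr$rho), "rho11"])
  }
  expect_equal(f(0.1, 381), f(0.2, 190.5), tolerance = 0.01)
})

test_that("for times long past tau4 all excited population reaches the product", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(),
                        t_start = -5, t_end = 800)
  n <- nrow(tr$rho)
  expect_lt(tr$rho[n, "rho22"], 1e-9)
  expect_lt(tr$rho[n, "rho33"], 1e-9)
  expect_lt(tr$rho[n, "rho44"], 1e-3)
  expect_equal(tr$rho[n, "rho55"], 1 - tr$rho[n, "rho11"],
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("invalid start times and lifetimes are rejected", {
  expect_error(integrate_bloch(level_scheme(), excitation_pulse(),
                               t_start = -0.5, t_end = 10), "too late")
  expect_error(integrate_bloch(level_scheme(), excitation_pulse(),
                               t_start = -5, t_end = -6), "exceed")
})

test_that("Bateman chain satisfies its boundary conditions and mass balance", {
  sch <- level_scheme()
  t <- seq(0, 50, by = 0.5)
  b <- bateman_cascade(0.37, sch, t)
  expect_equal(unname(b[1L, ]), c(0.37, 0, 0, 0))
  expect_lt(max(abs(rowSums(b) - 0.37)), 1e-12)
  expect_identical(bateman_cascade(0, sch, t), b * 0)
  ## frozen downstream rates leave a pure exponential in state 2
  b2 <- bateman_cascade(1, c(2, 0, 0), t)
  expect_equal(b2[, "rho22"], exp(-2 * t), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bateman_cascade(1, sch, c(-1, 2)), "non-negative")
  expect_error(bateman_cascade(1, c(-1, 2, 3), t), "non-negative")
})

test_that("degenerate-rate Bateman limiting forms match a numerical integration", {
  ## independent oracle: deSolve on the linear cascade
  ode_cascade <- function(g, t) {
    f <- function(t, y, p)
      list(c(-g[1] * y[1],
             g[1] * y[1] - g[2] * y[2],
             g[2] * y[2] - g[3] * y[3],
             g[3] * y[3]))
    unname(deSolve::ode(c(1, 0, 0, 0), t, f, NULL,
                        rtol = 1e-11, atol = 1e-11)[, -1])
  }
  t <- seq(0, 8, by = 0.25)
  for (g in list(c(2, 2, 0.5),       # g2 == g3
                 c(2, 0.5, 0.5),     # g3 == g4
                 c(2, 0.5, 2),       # g2 == g4
                 c(1.3, 1.3, 1.3),   # all equal
                 c(3, 1, 0.2))) {    # all distinct
    expect_lt(max(abs(bateman_cascade(1, g, t) - ode_cascade(g, t))), 1e-8)
  }
})

test_that("post-pulse Bloch dynamics match the closed-form cascade oracle", {
  sch <- level_scheme()
  tr <- integrate_bloch(sch, excitation_pulse(), t_end = 120)
  i0 <- which.min(abs(tr$t - 3))          # g(3 ps) < 1e-13: pulse over
  idx <- seq(i0, nrow(tr$rho), by = 40L)
  rho0 <- c(NA, tr$rho[i0, 2:5])
  oracle <- post_pulse_cascade(rho0, sch, tr$t[idx] - tr$t[i0])
  expect_lt(max(abs(tr$rho[idx, 2:5] - oracle)), 1e-6)
})

test_that("Rabi-frequency estimate follows the field convention", {
  expect_identical(
    estimate_rabi_frequency(excitation_pulse(peak_intensity = 2e9,
                                             transition_dipole_mu12 = 0)), 0)
  p1 <- excitation_pulse(peak_intensity = 1e9, transition_dipole_mu12 = 15)
  p2 <- excitation_pulse(peak_intensity = 2e9, transition_dipole_mu12 = 15)
  expect_equal(estimate_rabi_frequency(p2) / estimate_rabi_frequency(p1),
               sqrt(2), tolerance = 1e-12)
  ## printed pulse parameters give ~2.8 rad/ps under Omega = mu E0 / hbar
  expect_equal(estimate_rabi_frequency(p2), 2.7975, tolerance = 1e-4)
  expect_error(estimate_rabi_frequency(excitation_pulse()), "must both be set")
})

test_that("trace export round-trips through TSV", {
  tr <- integrate_bloch(level_scheme(), excitation_pulse(),
                        t_start = -5, t_end = -4.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bloch_trace(tr, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("t_ps", paste0("rho", 1:5, 1:5), "re_rho21", "im_rho21"))
  expect_equal(df$t_ps, tr$t, tolerance = 1e-8)
})
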