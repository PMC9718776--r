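#' Five-level reaction scheme
#'
#' Defines the sequential five-state photophysical scheme
#' S0 (1) --UV--> pipi* (2) --tau2--> pisigma* (3) --tau3--> hot S0 (4)
#' --tau4--> dissociated products (5), with decay rates
#' \eqn{\Gamma_{ii} = 1/\tau_i}. The coherence decay defaults to
#' \eqn{\Gamma_{21} = \Gamma_{22}/2} and the detuning to zero.
#'
#' @param tau2 Lifetime of the optically excited state, in fs.
#' @param tau3 Lifetime of the intermediate dark state, in ps.
#' @param tau4 Lifetime of the hot ground state against dissociation, in ps.
#' @param gamma21 Coherence decay rate in 1/ps; default `gamma22/2`.
#' @param delta_omega Detuning in rad/ps; default 0 (resonant excitation).
#'
#' @return An object of class `level_scheme`: a list with `tau2_fs`,
#'   `tau3_ps`, `tau4_ps`, the derived rates `gamma22`, `gamma33`,
#'   `gamma44` (1/ps), `gamma21` (1/ps) and `delta_omega` (rad/ps).
#' @examples
#' level_scheme()           # the published best-fit constants
#' level_scheme(tau2 = 300, tau3 = 10, tau4 = 80)
#' @export
level_scheme <- function(tau2 = 445, tau3 = 13, tau4 = 96,
                         gamma21 = NULL, delta_omega = 0) {
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0)
    stop("'tau2' must be a single positive number (fs)")
  if (!is.numeric(tau3) || length(tau3) != 1L || !is.finite(tau3) || tau3 <= 0)
    stop("'tau3' must be a single positive number (ps)")
  if (!is.numeric(tau4) || length(tau4) != 1L || !is.finite(tau4) || tau4 <= 0)
    stop("'tau4' must be a single positive number (ps)")
  gamma22 <- 1 / .fs2ps(tau2)
  if (is.null(gamma21)) gamma21 <- gamma22 / 2
  structure(list(
    tau2_fs = tau2, tau3_ps = tau3, tau4_ps = tau4,
    gamma22 = gamma22, gamma33 = 1 / tau3, gamma44 = 1 / tau4,
    gamma21 = gamma21, delta_omega = delta_omega
  ), class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  cat("Five-level reaction scheme\n")
  cat(sprintf("  tau2 = %.4g fs  (Gamma22 = %.4g /ps)\n", x$tau2_fs, x$gamma22))
  cat(sprintf("  tau3 = %.4g ps  (Gamma33 = %.4g /ps)\n", x$tau3_ps, x$gamma33))
  cat(sprintf("  tau4 = %.4g ps  (Gamma44 = %.4g /ps)\n", x$tau4_ps, x$gamma44))
  cat(sprintf("  Gamma21 = %.4g /ps, detuning = %.4g rad/ps\n",
              x$gamma21, x$delta_omega))
  invisible(x)
}

#' Excitation pulse description
#'
#' The pump pulse enters the equations of motion only through the product
#' \eqn{\Omega_0 g(t)} with the peak-normalized Gaussian envelope
#' \eqn{g(t) = \exp(-t^2 / 2\tau_{IRF}^2)}, where `tau_irf` is the
#' instrument-response width parameter.
#'
#' @param rabi_omega0 Peak Rabi frequency, rad/ps. Must be >= 0.
#' @param tau_irf IRF width parameter of `g(t)`, in fs.
#' @param transition_dipole_mu12 Optional transition dipole, in e pm; used
#'   only by [estimate_rabi_frequency()].
#' @param peak_intensity Optional pump peak intensity, W/cm^2; used only by
#'   [estimate_rabi_frequency()].
#' @return An object of class `excitation_pulse`.
#' @examples
#' excitation_pulse()  # published values: Omega0 = 3.4 rad/ps, tau_IRF = 381 fs
#' @export
excitation_pulse <- function(rabi_omega0 = 3.4, tau_irf = 381,
                             transition_dipole_mu12 = NULL,
                             peak_intensity = NULL) {
  if (!is.numeric(rabi_omega0) || length(rabi_omega0) != 1L ||
      !is.finite(rabi_omega0) || rabi_omega0 < 0)
    stop("'rabi_omega0' must be a single non-negative number (rad/ps)")
  if (!is.numeric(tau_irf) || length(tau_irf) != 1L || tau_irf <= 0)
    stop("'tau_irf' must be a single positive number (fs)")
  structure(list(
    rabi_omega0 = rabi_omega0, tau_irf_fs = tau_irf,
    transition_dipole_mu12 = transition_dipole_mu12,
    peak_intensity = peak_intensity
  ), class = "excitation_pulse")
}

#' @export
print.excitation_pulse <- function(x, ...) {
  cat(sprintf("Excitation pulse: Omega0 = %.4g rad/ps, tau_IRF = %.4g fs\n",
              x$rabi_omega0, x$tau_irf_fs))
  invisible(x)
}

#' IRF envelope g(t)
#'
#' The peak-normalized Gaussian instrument-response envelope
#' \eqn{g(t) = \exp(-t^2/2\tau_{IRF}^2)} (so `g(0) == 1`).
#'
#' @param t Times, ps.
#' @param pulse An [excitation_pulse()].
#' @return Envelope values in `[0, 1]`.
#' @export
irf_envelope <- function(t, pulse = excitation_pulse()) {
  tau <- .fs2ps(pulse$tau_irf_fs)
  exp(-0.5 * (t / tau)^2)
}

#' Estimate the Rabi frequency from pulse intensity and transition dipole
#'
#' Uses the convention \eqn{\Omega_0 = \mu_{12} E_0 / \hbar} with the peak
#' field \eqn{E_0 = \sqrt{2 I / (\epsilon_0 c)}} from the peak intensity.
#' This estimator is advisory: conventions for the field amplitude differ
#' between authors by factors of order one, so the Rabi frequency used in
#' the dynamics is always taken directly from the `rabi_omega0` field of
#' the pulse, never from this function.
#'
#' @param pulse An [excitation_pulse()] with `peak_intensity` (W/cm^2) and
#'   `transition_dipole_mu12` (e pm) set.
#' @return Rabi frequency in rad/ps.
#' @examples
#' p <- excitation_pulse(peak_intensity = 2e9, transition_dipole_mu12 = 15)
#' estimate_rabi_frequency(p)  # about 2.8 rad/ps
#' @export
estimate_rabi_frequency <- function(pulse) {
  if (is.null(pulse$peak_intensity) || is.null(pulse$transition_dipole_mu12))
    stop("'peak_intensity' and 'transition_dipole_mu12' must both be set")
  I_si <- pulse$peak_intensity * 1e4              # W/cm^2 -> W/m^2
  E0 <- sqrt(2 * I_si / (.const$eps0 * .const$c)) # V/m
  mu <- pulse$transition_dipole_mu12 * .const$e * 1e-12  # e pm -> C m
  omega_si <- mu * E0 / .const$hbar               # rad/s
  omega_si * 1e-12                                # rad/ps
}
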