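#' Wavepacket-oscillation modulation parameters
#'
#' The parent- and fragment-ion transients carry an undamped cosine
#' modulation \eqn{p^{osc}_j(t) = a_j + b_j \cos(\omega t + \phi)} from
#' coherently excited vibrational wavepacket dynamics; the water channel is
#' unmodulated. The offset/amplitude pair is per channel, frequency and
#' phase are shared. The defaults are the fixed values used in the global
#' fit: `a = 1.04, b = 0.14` (parent), `a = 0.92, b = 0.11` (fragment),
#' `omega = 3.77` rad/ps (period 1.67 ps, i.e. 0.60 THz or 20 cm^-1) and
#' `phi = 1.77`.
#'
#' @param a_parent,b_parent Offset and amplitude for the parent channel.
#' @param a_fragment,b_fragment Offset and amplitude for the fragment channel.
#' @param omega Shared angular frequency, rad/ps.
#' @param phi Shared phase, rad.
#' @return An object of class `oscillation_params`.
#' @export
oscillation_params <- function(a_parent = 1.04, b_parent = 0.14,
                               a_fragment = 0.92, b_fragment = 0.11,
                               omega = 3.77, phi = 1.77) {
  if (a_parent <= abs(b_parent) || a_fragment <= abs(b_fragment))
    stop("each offset 'a' must exceed |b| so the modulation stays positive")
  if (omega < 0) stop("'omega' must be non-negative")
  structure(list(a_parent = a_parent, b_parent = b_parent,
                 a_fragment = a_fragment, b_fragment = b_fragment,
                 omega = omega, phi = phi),
            class = "oscillation_params")
}

#' @export
print.oscillation_params <- function(x, ...) {
  cat(sprintf("Oscillation: omega = %.4g rad/ps (period %.3g ps), phi = %.3g\n",
              x$omega, oscillation_period(x), x$phi))
  cat(sprintf("  parent   a = %.3g, b = %.3g\n", x$a_parent, x$b_parent))
  cat(sprintf("  fragment a = %.3g, b = %.3g\n", x$a_fragment, x$b_fragment))
  invisible(x)
}

#' Period and wavenumber of the oscillation
#'
#' `oscillation_period()` returns \eqn{2\pi/\omega} in ps;
#' `oscillation_wavenumber()` converts the same frequency to cm^-1
#' (the vibrational level spacing the wavepacket beat corresponds to).
#'
#' @param osc An [oscillation_params()].
#' @return Period in ps, or wavenumber in cm^-1.
#' @export
oscillation_period <- function(osc) 2 * pi / osc$omega

#' @rdname oscillation_period
#' @export
oscillation_wavenumber <- function(osc) {
  f_hz <- osc$omega / (2 * pi) * 1e12        # rad/ps -> Hz
  f_hz / (.const$c * 100)                    # Hz -> cm^-1
}

.posc <- function(t, a, b, omega, phi) a + b * cos(omega * t + phi)

#' Channel weight coefficients of the ion-signal model
#'
#' The three ion signals are linear combinations of the probe-convolved
#' populations: parent = `sum(A[i] rho'_ii, i = 2..4)` times its
#' oscillation factor, fragment = `sum(B[i] rho'_ii, i = 2..5)` times its
#' oscillation factor, water = `C rho'_55` (no modulation).
#'
#' @param A Numeric length 3, weights of states 2..4 in the parent channel.
#' @param B Numeric length 4, weights of states 2..5 in the fragment channel.
#' @param C Single weight of state 5 in the water channel.
#' @return An object of class `signal_coefficients`.
#' @export
signal_coefficients <- function(A = c(1.0, 0.55, 0.30),
                                B = c(0.25, 0.45, 0.65, 0.80),
                                C = 0.5) {
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C)
  if (length(A) != 3L || length(B) != 4L || length(C) != 1L)
    stop("'A' must have length 3 (states 2..4), 'B' length 4 (states 2..5), ",
         "'C' length 1")
  if (any(!is.finite(c(A, B, C))) || any(c(A, B, C) < 0))
    stop("all coefficients must be finite and non-negative")
  structure(list(A = A, B = B, C = C), class = "signal_coefficients")
}

#' Delay-indexed ion-yield curve for one mass channel
#'
#' @param delays Pump-probe delays in ps, strictly increasing (possibly
#'   non-uniform).
#' @param yields Ion signal per delay (arbitrary units).
#' @param sigma 1-sigma uncertainty per point, `> 0`.
#' @param channel Channel label, one of `"parent"`, `"fragment"`, `"water"`
#'   (or any other label for auxiliary curves).
#' @return An object of class `ion_yield_curve` (a data.frame with a
#'   `channel` attribute).
#' @export
ion_yield_curve <- function(delays, yields, sigma, channel) {
  if (any(diff(delays) <= 0)) stop("'delays' must be strictly increasing")
  if (length(yields) != length(delays) || length(sigma) != length(delays))
    stop("'yields' and 'sigma' must match 'delays' in length")
  if (any(sigma <= 0)) stop("'sigma' must be positive everywhere")
  structure(data.frame(delay_ps = delays, yield = yields, sigma = sigma),
            channel = channel, class = c("ion_yield_curve", "data.frame"))
}

#' Convolve populations with the probe-pulse intensity envelope
#'
#' Convolves each population of a Maxwell-Bloch trace with an
#' area-normalized Gaussian representing the ionizing probe pulse
#' (default FWHM 70 fs). The convolution is computed exactly for the
#' piecewise-linear interpolant of the trace (closed form in the normal
#' cdf/pdf), so constant segments are reproduced exactly and a step input
#' yields the analytic smoothed step.
#'
#' @param trace A `bloch_trace` from [integrate_bloch()], or a list with
#'   fields `t` and `rho` (matrix of populations by column).
#' @param probe_fwhm Probe intensity-envelope FWHM, fs.
#' @param at Optional times (ps) at which to evaluate the convolved
#'   populations; default: the trace grid itself.
#' @return A list with `t` (the evaluation times) and `rho` (matrix of
#'   convolved populations, same columns as the input).
#' @export
convolve_probe <- function(trace, probe_fwhm = 70, at = NULL) {
  t <- trace$t
  rho <- as.matrix(trace$rho)
  sig <- .fs2ps(.fwhm2sigma(probe_fwhm))
  fine_dt <- min(diff(t))
  if (fine_dt > probe_fwhm / 10 / 1000)
    stop("trace grid too coarse: need >= 10 points per probe FWHM in the ",
         "fine region")
  xout <- if (is.null(at)) t else as.numeric(at)
  out <- matrix(NA_real_, length(xout), ncol(rho),
                dimnames = list(NULL, colnames(rho)))
  for (j in seq_len(ncol(rho)))
    out[, j] <- .Call(C_gauss_conv_plin, as.numeric(t), as.numeric(rho[, j]),
                      xout, sig)
  list(t = xout, rho = out)
}

#' Model ion yields from convolved populations
#'
#' Evaluates the three-channel ion-signal model at the requested delays:
#' parent and fragment channels are oscillation-modulated linear
#' combinations of the convolved populations of states 2..4 and 2..5, the
#' water channel is proportional to the convolved population of state 5.
#' Values are interpolated linearly from the convolved trace grid; no
#' extrapolation is allowed.
#'
#' @param conv Convolved populations from [convolve_probe()] (full-grid).
#' @param coeffs A [signal_coefficients()].
#' @param osc An [oscillation_params()].
#' @param delays Delays (ps) at which to evaluate, within the trace range.
#' @param baseline Optional numeric length 3 (parent, fragment, water)
#'   constant baseline added to each channel; default zeros.
#' @return Named list of three [ion_yield_curve()]s (`parent`, `fragment`,
#'   `water`) with `sigma` set to `NA`-free placeholder 1 (model curves
#'   carry no noise).
#' @export
model_ion_yields <- function(conv, coeffs, osc, delays, baseline = c(0, 0, 0)) {
  rng <- range(conv$t)
  if (any(delays < rng[1L] | delays > rng[2L]))
    stop("requested delays fall outside the integrated time range")
  if (any(diff(delays) <= 0)) stop("'delays' must be strictly increasing")
  interp <- function(col) stats::approx(conv$t, conv$rho[, col], xout = delays,
                                        rule = 1)$y
  r22 <- interp("rho22"); r33 <- interp("rho33")
  r44 <- interp("rho44"); r55 <- interp("rho55")
  parent <- .posc(delays, osc$a_parent, osc$b_parent, osc$omega, osc$phi) *
    (coeffs$A[1L] * r22 + coeffs$A[2L] * r33 + coeffs$A[3L] * r44)
  fragment <- .posc(delays, osc$a_fragment, osc$b_fragment, osc$omega, osc$phi) *
    (coeffs$B[1L] * r22 + coeffs$B[2L] * r33 + coeffs$B[3L] * r44 +
       coeffs$B[4L] * r55)
  water <- coeffs$C * r55
  one <- rep(1, length(delays))
  list(parent   = ion_yield_curve(delays, parent + baseline[1L], one, "parent"),
       fragment = ion_yield_curve(delays, fragment + baseline[2L], one, "fragment"),
       water    = ion_yield_curve(delays, water + baseline[3L], one, "water"))
}

#' Fit the oscillation parameters from a high-resolution transient
#'
#' Least-squares fit of `envelope(t) * (a + b cos(omega t + phi))` to a
#' single densely sampled transient, mirroring the procedure of optimizing
#' the modulation parameters once on a high-resolution measurement and then
#' fixing them in the global kinetics fit. The slowly varying envelope is a
#' polynomial normalized to 1 at the mean delay, so `a` keeps the absolute
#' scale.
#'
#' @param curve An [ion_yield_curve()] spanning at least 3 oscillation
#'   periods, sampled at >= 4 points per period.
#' @param envelope `"constant"`, `"linear"` or `"quadratic"` polynomial
#'   envelope.
#' @param omega_init Optional starting angular frequency (rad/ps); default:
#'   dominant non-zero FFT frequency of the detrended signal.
#' @return A list with elements `a`, `b`, `omega`, `phi`, the envelope
#'   polynomial coefficients, and the fit RSS.
#' @export
fit_oscillation <- function(curve, envelope = c("constant", "linear", "quadratic"),
                            omega_init = NULL) {
  envelope <- match.arg(envelope)
  t <- curve$delay_ps; y <- curve$yield
  n <- length(t)
  dt <- stats::median(diff(t))

  if (is.null(omega_init)) {
    ## dominant frequency of the detrended, uniformly resampled signal
    tu <- seq(min(t), max(t), by = dt)
    yu <- stats::approx(t, y, xout = tu)$y
    yu <- yu - stats::fitted(stats::lm(yu ~ poly(tu, 2)))
    sp <- stats::fft(yu)
    freqs <- seq_len(length(tu)) - 1L
    half <- 2:floor(length(tu) / 2)
    k <- half[which.max(Mod(sp[half]))]
    omega_init <- 2 * pi * (k - 1L) / (length(tu) * dt)
  }
  period <- 2 * pi / omega_init
  if ((max(t) - min(t)) < 3 * period)
    stop("curve must span at least 3 oscillation periods")
  if (dt > period / 4)
    stop("undersampled transient: fewer than 4 points per period ",
         "(aliasing); use a finer delay scan")

  t0 <- mean(t)
  deg <- switch(envelope, constant = 0L, linear = 1L, quadratic = 2L)
  ## parameters: a, b, omega, phi, e1..e_deg
  resid_fn <- function(p) {
    env <- rep(1, n)
    if (deg >= 1L) for (d in seq_len(deg)) env <- env + p[4L + d] * (t - t0)^d
    y - env * (p[1L] + p[2L] * cos(p[3L] * t + p[4L]))
  }
  ## phase/amplitude init by linear regression at omega_init
  X <- cbind(1, cos(omega_init * t), sin(omega_init * t))
  cf <- stats::lm.fit(X, y)$coefficients
  b0 <- sqrt(cf[2L]^2 + cf[3L]^2)
  phi0 <- atan2(-cf[3L], cf[2L])
  p0 <- unname(c(cf[1L], b0, omega_init, phi0, rep(0, deg)))
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  ## canonical form: b >= 0, phi in (-pi, pi]
  if (p[2L] < 0) { p[2L] <- -p[2L]; p[4L] <- p[4L] + pi }
  p[4L] <- ((p[4L] + pi) %% (2 * pi)) - pi
  list(a = p[1L], b = p[2L], omega = p[3L], phi = p[4L],
       envelope = if (deg) p[5L:(4L + deg)] else numeric(0),
       rss = sum(fit$fvec^2), niter = fit$niter)
}
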