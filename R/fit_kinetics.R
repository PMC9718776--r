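## Assemble the sigma-weighted residual vector for a parameter vector
## p = (log tau2_fs, log tau3_ps, log tau4_ps, A2..A4, B2..B5, C [, b1..b3]).
## The Bloch integration and probe convolution are cached on the tau
## triple: Levenberg-Marquardt finite-difference steps in the linear
## coefficients reuse the last trace.
.kin_residual_factory <- function(curves, pulse, osc, probe_fwhm,
                                  t_start, t_end, tolerance,
                                  baseline_mode, negwin) {
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL
  channels <- names(curves)
  all_delays <- sort(unique(unlist(lapply(curves, `[[`, "delay_ps"))))
  function(p) {
    taus <- exp(p[1:3])
    key <- paste(format(taus, digits = 17), collapse = ",")
    if (is.null(cache$key) || cache$key != key) {
      scheme <- level_scheme(tau2 = taus[1L], tau3 = taus[2L], tau4 = taus[3L])
      trace <- integrate_bloch(scheme, pulse, t_start = t_start,
                               t_end = t_end, tolerance = tolerance)
      cache$conv <- convolve_probe(trace, probe_fwhm, at = all_delays)
      cache$key <- key
    }
    coeffs <- signal_coefficients(A = p[4:6], B = p[7:10], C = p[11L])
    m <- model_ion_yields(cache$conv, coeffs, osc, all_delays)
    res <- lapply(seq_along(channels), function(i) {
      ch <- channels[i]
      cu <- curves[[ch]]
      mi <- m[[ch]]$yield[match(cu$delay_ps, all_delays)]
      yi <- cu$yield
      if (baseline_mode == "fit") {
        mi <- mi + p[11L + i]
      } else if (baseline_mode == "subtract") {
        ## correct model and data with the same estimator
        yi <- yi - mean(yi[negwin[[ch]]])
        mi <- mi - mean(mi[negwin[[ch]]])
      }
      (yi - mi) / cu$sigma
    })
    unlist(res, use.names = FALSE)
  }
}

#' Globally fit the five-level reaction model to three ion-yield channels
#'
#' Joint weighted Levenberg-Marquardt fit of the time constants
#' (tau2, tau3, tau4) and the channel coefficients (A2..A4, B2..B5, C) of
#' the ion-signal model to parent-, fragment- and water-channel transients.
#' At every iteration the five-level Maxwell-Bloch equations are
#' re-integrated, the populations are convolved with the probe envelope,
#' and the fixed oscillation modulation is applied; the objective is the
#' reduced chi-square of the simulated against the background-corrected
#' measured signals, weighted by the per-point 1-sigma uncertainties.
#' Time constants are fitted in log-space (positivity), coefficients are
#' bounded below by zero.
#'
#' The constant negative-delay background can be handled three ways:
#' `"fit"` (default) adds one free constant per channel to the model, so
#' its uncertainty is propagated into the time constants; `"subtract"`
#' removes the mean over delays before `baseline_before` from the data
#' *and applies the same estimator to the model*, which keeps the
#' objective consistent even though the model is not exactly zero at the
#' earliest measured delays; `"none"` assumes pre-corrected input.
#'
#' @param curves Named list with elements `parent`, `fragment`, `water`,
#'   each an [ion_yield_curve()]. Delay grids may differ between channels
#'   and be non-uniform.
#' @param scheme_init A [level_scheme()] holding starting time constants.
#' @param pulse An [excitation_pulse()] (fixed during the fit).
#' @param osc An [oscillation_params()] (fixed during the fit).
#' @param probe_fwhm Probe intensity FWHM, fs.
#' @param coeffs_init Optional [signal_coefficients()] start; default: a
#'   weighted linear least-squares solve at `scheme_init`.
#' @param baseline `"fit"`, `"subtract"` or `"none"`; see Details.
#' @param baseline_before Delay threshold (ps) defining the negative-delay
#'   window used to initialize (`"fit"`) or estimate (`"subtract"`) the
#'   baseline.
#' @param tolerance ODE solver tolerance used inside the fit.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#'
#' @return An object of class `kinetics_fit` with components `tau` (named
#'   fs/ps estimates), `tau_se`, `coefficients`, `coefficients_se`,
#'   `chi2red`, `r_squared` (joint), `r_squared_channel`, `dof`, `vcov`
#'   (natural scale), `baseline`, `convergence`, and the inputs needed by
#'   the methods (`print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `plot`, `df.residual`).
#' @examples
#' \donttest{
#' truth <- ground_truth()
#' curves <- generate_ion_yield_scan(truth, paper_scan_design(), seed = 1)
#' fit <- fit_reaction_model(curves)
#' summary(fit)
#' }
#' @export
fit_reaction_model <- function(curves,
                               scheme_init = level_scheme(),
                               pulse = excitation_pulse(),
                               osc = oscillation_params(),
                               probe_fwhm = 70,
                               coeffs_init = NULL,
                               baseline = c("fit", "subtract", "none"),
                               baseline_before = -0.5,
                               tolerance = 1e-9,
                               max_iter = 100) {
  baseline_mode <- match.arg(baseline)
  stopifnot(is.list(curves),
            all(c("parent", "fragment", "water") %in% names(curves)))
  curves <- curves[c("parent", "fragment", "water")]
  for (cu in curves)
    if (any(cu$sigma <= 0)) stop("all 'sigma' must be positive for fitting")

  negwin <- lapply(curves, function(cu) cu$delay_ps < baseline_before)
  bl0 <- vapply(names(curves), function(ch) {
    if (any(negwin[[ch]])) mean(curves[[ch]]$yield[negwin[[ch]]]) else 0
  }, 0)
  if (baseline_mode == "subtract" && !all(vapply(negwin, any, TRUE)))
    stop("baseline = \"subtract\" needs delays before ", baseline_before,
         " ps in every channel")

  all_min <- min(vapply(curves, function(cu) min(cu$delay_ps), 0))
  all_max <- max(vapply(curves, function(cu) max(cu$delay_ps), 0))
  t_start <- min(-5, all_min - 0.5)
  t_end <- all_max + 0.5

  resid_fn <- .kin_residual_factory(curves, pulse, osc, probe_fwhm,
                                    t_start, t_end, tolerance,
                                    baseline_mode, negwin)

  ## starting coefficients: weighted linear LS at the initial scheme
  if (is.null(coeffs_init)) {
    trace0 <- integrate_bloch(scheme_init, pulse, t_start = t_start,
                              t_end = t_end, tolerance = tolerance)
    coeffs_init <- .init_coefficients(curves, trace0, osc, probe_fwhm, bl0)
  }
  p0 <- c(log(scheme_init$tau2_fs), log(scheme_init$tau3_ps),
          log(scheme_init$tau4_ps),
          coeffs_init$A, coeffs_init$B, coeffs_init$C)
  lower <- c(rep(-Inf, 3), rep(0, 8))
  par_names <- c("tau2_fs", "tau3_ps", "tau4_ps",
                 paste0("A", 2:4), paste0("B", 2:5), "C")
  if (baseline_mode == "fit") {
    p0 <- c(p0, bl0)
    lower <- c(lower, rep(-Inf, 3))
    par_names <- c(par_names, paste0("bg_", names(curves)))
  }

  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = 1e-10,
                                         ftol = 1e-10))
  if (fit$info %in% c(0, 5))
    warning("Levenberg-Marquardt did not converge (info = ", fit$info,
            "): ", fit$message)

  p <- fit$par
  taus <- exp(p[1:3])
  npar <- length(p)
  ndata <- length(fit$fvec)
  dof <- ndata - npar
  if (dof <= 0) stop("fewer data points than parameters")
  chi2red <- sum(fit$fvec^2) / dof

  ## covariance: (J'J)^-1 scaled by reduced chi-square; taus by delta method
  vc_nat <- matrix(NA_real_, npar, npar)
  se_nat <- rep(NA_real_, npar)
  vc <- tryCatch(solve(fit$hessian) * chi2red, error = function(e) NULL)
  if (!is.null(vc)) {
    D <- diag(c(taus, rep(1, npar - 3)))
    vc_nat <- D %*% vc %*% D
    se_nat <- sqrt(pmax(diag(vc_nat), 0))
  }
  dimnames(vc_nat) <- list(par_names, par_names)

  est <- stats::setNames(c(taus, p[-(1:3)]), par_names)
  bl_fit <- if (baseline_mode == "fit") {
    stats::setNames(p[12:14], names(curves))
  } else if (baseline_mode == "subtract") bl0 else
    stats::setNames(numeric(3), names(curves))

  fitted_values <- .kin_fitted(curves, taus, p[4:11], pulse, osc, probe_fwhm,
                               t_start, t_end, tolerance,
                               baseline_mode, bl_fit, negwin)

  ## weighted R-squared, jointly and per channel, on the corrected data
  ycorr <- lapply(names(curves), function(ch) {
    y <- curves[[ch]]$yield
    if (baseline_mode == "subtract") y - mean(y[negwin[[ch]]]) else y
  })
  names(ycorr) <- names(curves)
  wres <- split(fit$fvec, rep(names(curves),
                              vapply(curves, nrow, 0L)))[names(curves)]
  r2ch <- vapply(names(curves), function(ch) {
    w <- 1 / curves[[ch]]$sigma^2
    ybar <- sum(w * ycorr[[ch]]) / sum(w)
    1 - sum(wres[[ch]]^2) / sum(w * (ycorr[[ch]] - ybar)^2)
  }, 0)
  ytot <- unlist(ycorr)
  wtot <- unlist(lapply(curves, function(cu) 1 / cu$sigma^2))
  ybar <- sum(wtot * ytot) / sum(wtot)
  r2 <- 1 - sum(fit$fvec^2) / sum(wtot * (ytot - ybar)^2)

  structure(list(
    tau = est[1:3], tau_se = stats::setNames(se_nat[1:3], par_names[1:3]),
    coefficients = est, coefficients_se = stats::setNames(se_nat, par_names),
    chi2red = chi2red, r_squared = r2, r_squared_channel = r2ch,
    dof = dof, ndata = ndata, vcov = vc_nat,
    baseline = bl_fit, baseline_mode = baseline_mode,
    curves = curves,
    scheme = level_scheme(tau2 = taus[1L], tau3 = taus[2L], tau4 = taus[3L]),
    pulse = pulse, osc = osc, probe_fwhm = probe_fwhm,
    fitted_values = fitted_values,
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter, deviance = sum(fit$fvec^2))
  ), class = "kinetics_fit")
}

## weighted linear LS for the coefficients at fixed scheme (start values);
## the negative-delay baseline estimate is removed from the data first
.init_coefficients <- function(curves, trace, osc, probe_fwhm, bl0) {
  val <- function(cu, cols, b0, a = NULL, b = NULL) {
    cv <- convolve_probe(trace, probe_fwhm, at = cu$delay_ps)
    X <- cv$rho[, cols, drop = FALSE]
    if (!is.null(a))
      X <- X * .posc(cu$delay_ps, a, b, osc$omega, osc$phi)
    w <- 1 / cu$sigma
    cf <- stats::lm.fit(X * w, (cu$yield - b0) * w)$coefficients
    pmax(cf, 1e-6)
  }
  A <- val(curves$parent, c("rho22", "rho33", "rho44"), bl0[["parent"]],
           osc$a_parent, osc$b_parent)
  B <- val(curves$fragment, c("rho22", "rho33", "rho44", "rho55"),
           bl0[["fragment"]], osc$a_fragment, osc$b_fragment)
  C <- val(curves$water, "rho55", bl0[["water"]])
  signal_coefficients(A = unname(A), B = unname(B), C = unname(C))
}

.kin_fitted <- function(curves, taus, coefvec, pulse, osc, probe_fwhm,
                        t_start, t_end, tolerance,
                        baseline_mode = "none",
                        bl = c(parent = 0, fragment = 0, water = 0),
                        negwin = NULL) {
  scheme <- level_scheme(tau2 = taus[1L], tau3 = taus[2L], tau4 = taus[3L])
  trace <- integrate_bloch(scheme, pulse, t_start = t_start, t_end = t_end,
                           tolerance = tolerance)
  coeffs <- signal_coefficients(A = coefvec[1:3], B = coefvec[4:7],
                                C = coefvec[8L])
  lapply(stats::setNames(nm = names(curves)), function(ch) {
    cv <- convolve_probe(trace, probe_fwhm, at = curves[[ch]]$delay_ps)
    m <- model_ion_yields(cv, coeffs, osc, curves[[ch]]$delay_ps)[[ch]]$yield
    if (baseline_mode == "fit") m + bl[[ch]]
    else if (baseline_mode == "subtract") m - mean(m[negwin[[ch]]])
    else m
  })
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("Global five-level reaction-model fit\n")
  cat(sprintf("  tau2 = %.0f +/- %.0f fs\n", x$tau["tau2_fs"],
              x$tau_se["tau2_fs"]))
  cat(sprintf("  tau3 = %.1f +/- %.1f ps\n", x$tau["tau3_ps"],
              x$tau_se["tau3_ps"]))
  cat(sprintf("  tau4 = %.0f +/- %.0f ps\n", x$tau["tau4_ps"],
              x$tau_se["tau4_ps"]))
  cat(sprintf("  reduced chi-square = %.3f,  R^2 = %.4f  (%d points, %d dof)\n",
              x$chi2red, x$r_squared, x$ndata, x$dof))
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$coefficients_se)
  structure(list(coefficients = tab, chi2red = object$chi2red,
                 r_squared = object$r_squared,
                 r_squared_channel = object$r_squared_channel,
                 dof = object$dof, baseline = object$baseline,
                 baseline_mode = object$baseline_mode,
                 convergence = object$convergence),
            class = "summary.kinetics_fit")
}

#' @export
print.summary.kinetics_fit <- function(x, ...) {
  cat("Global five-level reaction-model fit\n\nParameters:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nReduced chi-square: %.3f on %d degrees of freedom\n",
              x$chi2red, x$dof))
  cat(sprintf("R^2 (joint): %.4f;  per channel: %s\n", x$r_squared,
              paste(sprintf("%s %.4f", names(x$r_squared_channel),
                            x$r_squared_channel), collapse = ", ")))
  cat(sprintf("Baseline handling: %s (%s)\n", x$baseline_mode,
              paste(sprintf("%s %.4g", names(x$baseline), x$baseline),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) object$coefficients

#' @export
vcov.kinetics_fit <- function(object, ...) object$vcov

#' @export
df.residual.kinetics_fit <- function(object, ...) object$dof

#' @export
fitted.kinetics_fit <- function(object, ...) object$fitted_values

#' @export
residuals.kinetics_fit <- function(object, type = c("response", "weighted"),
                                   ...) {
  type <- match.arg(type)
  lapply(stats::setNames(nm = names(object$curves)), function(ch) {
    y <- object$curves[[ch]]$yield
    if (object$baseline_mode == "subtract")
      y <- y - object$baseline[[ch]]
    r <- y - object$fitted_values[[ch]]
    if (type == "weighted") r / object$curves[[ch]]$sigma else r
  })
}

#' Predict model ion yields from a fitted reaction model
#'
#' @param object A `kinetics_fit`.
#' @param delays Delays (ps) at which to evaluate; default: the delays of
#'   the fitted data (per channel).
#' @param ... Unused.
#' @return Named list of model curves (without baseline), one numeric
#'   vector per channel.
#' @export
predict.kinetics_fit <- function(object, delays = NULL, ...) {
  curves <- object$curves
  if (!is.null(delays))
    for (ch in names(curves))
      curves[[ch]] <- ion_yield_curve(delays, rep(0, length(delays)),
                                      rep(1, length(delays)), ch)
  .kin_fitted(curves, object$tau, object$coefficients[4:11], object$pulse,
              object$osc, object$probe_fwhm,
              t_start = min(-5, min(vapply(curves, function(cu)
                min(cu$delay_ps), 0)) - 0.5),
              t_end = max(vapply(curves, function(cu)
                max(cu$delay_ps), 0)) + 0.5,
              tolerance = 1e-9)
}

#' Plot a fitted reaction model over the data
#'
#' Three stacked panels (parent, fragment, water) with the data, 1-sigma
#' error bars and the fitted model (including the fitted baseline).
#'
#' @param x A `kinetics_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kinetics_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (ch in names(x$curves)) {
    cu <- x$curves[[ch]]
    y <- cu$yield
    if (x$baseline_mode == "subtract") y <- y - x$baseline[[ch]]
    graphics::plot(cu$delay_ps, y, pch = 16, cex = 0.6,
                   xlab = "pump-probe delay (ps)",
                   ylab = "ion yield (arb. u.)", main = ch, ...)
    graphics::arrows(cu$delay_ps, y - cu$sigma, cu$delay_ps, y + cu$sigma,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
    graphics::lines(cu$delay_ps, x$fitted_values[[ch]], col = "red3", lwd = 1.5)
  }
  invisible(x)
}
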