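#' Classical ion-dipole model for the delay evolution of the mean TKER
#'
#' After statistical dissociation the water cation and the neutral
#' chromophore repel each other through the charge-dipole interaction
#' \eqn{V = q \mu \cos\theta / (4\pi\epsilon_0 R^2)}. With the fragments
#' separating linearly, \eqn{R(t) = R_{eq} + v (t - t_d)}, the mean total
#' kinetic energy release follows
#' \eqn{TKER(t) = E_{pump} + V(t) - E_a}, decaying monotonically to the
#' asymptote \eqn{E_{pump} - E_a}.
#'
#' Defaults are the published best-fit parameters: `R_eq = 490` pm,
#' `v = 12` m/s, `t_d = 51` ps, `theta = 38` deg, `E_a = 4.57` eV, with the
#' fixed constants `mu = 1.96` D, `q = 1` e, `E_pump = 4.61` eV.
#'
#' @param R_eq Equilibrium charge-dipole separation, pm.
#' @param v Separation speed, m/s (numerically equal to pm/ps).
#' @param t_d Dissociation delay, ps.
#' @param theta Interaction angle, degrees (`cos(theta) > 0` assumed).
#' @param E_a Asymptotic internal energy of the fragments, eV.
#' @param mu Dipole moment of the neutral co-fragment, D (fixed).
#' @param q Fragment-ion charge in units of e (fixed).
#' @param E_pump Pump-photon energy, eV (fixed).
#' @return An object of class `ion_dipole_model`.
#' @export
ion_dipole_model <- function(R_eq = 490, v = 12, t_d = 51, theta = 38,
                             E_a = 4.57, mu = 1.96, q = 1, E_pump = 4.61) {
  if (R_eq <= 0) stop("'R_eq' must be positive (pm)")
  if (v < 0) stop("'v' must be non-negative (m/s)")
  structure(list(R_eq = R_eq, v = v, t_d = t_d, theta = theta, E_a = E_a,
                 mu = mu, q = q, E_pump = E_pump),
            class = "ion_dipole_model")
}

#' @export
print.ion_dipole_model <- function(x, ...) {
  cat("Ion-dipole separation model\n")
  cat(sprintf("  R_eq = %.4g pm, v = %.4g m/s, t_d = %.4g ps, ",
              x$R_eq, x$v, x$t_d))
  cat(sprintf("theta = %.4g deg, E_a = %.4g eV\n", x$theta, x$E_a))
  cat(sprintf("  fixed: mu = %.3g D, q = %g e, E_pump = %.3g eV; ",
              x$mu, x$q, x$E_pump))
  cat(sprintf("asymptotic TKER = %.1f meV\n", 1000 * (x$E_pump - x$E_a)))
  invisible(x)
}

#' Charge-dipole interaction energy
#'
#' \eqn{V = q \mu \cos\theta / (4\pi\epsilon_0 R^2)} in eV, neglecting
#' higher-order terms (ion-induced dipole, dipole-dipole).
#'
#' @param R Separation, pm (`> 0`).
#' @param theta Angle between dipole axis and separation vector, degrees.
#' @param mu Dipole moment, D.
#' @param q Ion charge in units of e.
#' @return Interaction energy, eV.
#' @examples
#' ion_dipole_potential(490, 38)  # about 0.19 eV
#' @export
ion_dipole_potential <- function(R, theta, mu = 1.96, q = 1) {
  if (any(R <= 0)) stop("'R' must be positive")
  R_m <- R * 1e-12
  mu_cm <- mu * .const$debye
  V_j <- q * .const$e * mu_cm * cos(theta * pi / 180) /
    (4 * pi * .const$eps0 * R_m^2)
  V_j / .const$ev
}

#' Mean TKER as a function of pump-probe delay
#'
#' Evaluates \eqn{TKER(t) = E_{pump} - E_a + V(R_{eq} + v (t - t_d))} in
#' eV. The model is undefined before the dissociation delay `t_d`; by
#' default evaluation there is an error, or the values are masked to `NA`.
#'
#' @param model An [ion_dipole_model()].
#' @param t Delays, ps.
#' @param mask_before_td If `TRUE`, return `NA` for `t < t_d` instead of
#'   erroring.
#' @return TKER in eV (monotone non-increasing for `v > 0`,
#'   `cos(theta) > 0`; asymptote `E_pump - E_a`).
#' @export
tker_evolution <- function(model, t, mask_before_td = FALSE) {
  stopifnot(inherits(model, "ion_dipole_model"))
  bad <- t < model$t_d
  if (any(bad) && !mask_before_td)
    stop("the ion-dipole model is undefined for t < t_d = ", model$t_d,
         " ps; use mask_before_td = TRUE to mask")
  R <- model$R_eq + model$v * (t - model$t_d)   # v m/s == pm/ps
  out <- model$E_pump - model$E_a +
    ion_dipole_potential(pmax(R, .Machine$double.eps), model$theta,
                         model$mu, model$q)
  out[bad] <- NA_real_
  out
}

#' Fit the ion-dipole model to a mean-TKER series
#'
#' Five-parameter weighted Levenberg-Marquardt fit of (`R_eq`, `v`, `t_d`,
#' `theta`, `E_a`) to the delay evolution of the mean TKER, with `mu`, `q`
#' and `E_pump` held fixed. Since the separation is linear in time, only
#' the combinations (`R_eq - v t_d`, `v`, amplitude `q mu cos(theta)`,
#' offset `E_pump - E_a`) are identifiable: `R_eq` and `t_d` are exactly
#' degenerate along `dR_eq = v dt_d`. The full five-parameter fit is still
#' performed (matching the published procedure); `summary()` reports the
#' parameter correlations and the identifiable combinations.
#'
#' @param series A data.frame with columns `delay_ps`, `mean_tker_meV` and
#'   optionally `sigma_meV` (as produced by [mean_tker_series()] or
#'   [generate_mean_tker()]).
#' @param init An [ion_dipole_model()] with starting values; its `mu`,
#'   `q`, `E_pump` are taken as the fixed constants.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `ion_dipole_fit` with `model` (the fitted
#'   [ion_dipole_model()]), `estimate`, `se`, `vcov`, `correlation`,
#'   `identifiable` (named identifiable combinations), `chi2red`, `dof`,
#'   plus `print`, `summary`, `coef`, `vcov`, `predict`, `fitted`,
#'   `residuals` and `plot` methods.
#' @export
fit_ion_dipole <- function(series, init = ion_dipole_model(), max_iter = 200) {
  stopifnot(is.data.frame(series),
            all(c("delay_ps", "mean_tker_meV") %in% names(series)))
  t <- series$delay_ps
  y <- series$mean_tker_meV / 1000      # eV
  if (length(t) < 8L)
    stop("need at least 8 delay points to fit five parameters")
  sig <- if (!is.null(series$sigma_meV) && all(is.finite(series$sigma_meV)) &&
             all(series$sigma_meV > 0))
    series$sigma_meV / 1000 else rep(1, length(t))

  td_max <- min(t) - 1e-6
  if (init$t_d >= td_max)
    warning("starting t_d is not below the first delay; clamped")
  p0 <- c(init$R_eq, init$v, min(init$t_d, td_max - 1), init$theta, init$E_a)
  lower <- c(1, 0, -Inf, 0, -Inf)
  upper <- c(Inf, Inf, td_max, 89.9, Inf)

  resid_fn <- function(p) {
    m <- ion_dipole_model(R_eq = p[1L], v = p[2L], t_d = p[3L],
                          theta = p[4L], E_a = p[5L],
                          mu = init$mu, q = init$q, E_pump = init$E_pump)
    (y - tker_evolution(m, t)) / sig
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-12, ftol = 1e-12))
  if (fit$info %in% c(0, 5))
    warning("ion-dipole fit did not converge: ", fit$message)
  p <- fit$par
  if (p[3L] >= td_max - 1e-9)
    warning("fitted t_d reached the first measured delay; t_d is outside ",
            "the constrained range of the data")
  nm <- c("R_eq_pm", "v_mps", "t_d_ps", "theta_deg", "E_a_eV")
  est <- stats::setNames(p, nm)
  dof <- length(t) - length(p)
  chi2red <- sum(fit$fvec^2) / max(dof, 1L)

  vc <- tryCatch(solve(fit$hessian) * chi2red, error = function(e) {
    ## the (R_eq, t_d) direction is flat: fall back to the pseudo-inverse
    ev <- eigen(fit$hessian, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    (ev$vectors[, keep, drop = FALSE] %*%
       diag(1 / ev$values[keep], sum(keep)) %*%
       t(ev$vectors[, keep, drop = FALSE])) * chi2red
  })
  dimnames(vc) <- list(nm, nm)
  se <- stats::setNames(sqrt(pmax(diag(vc), 0)), nm)
  d <- se; d[d == 0] <- 1
  corr <- vc / outer(d, d)

  model <- ion_dipole_model(R_eq = p[1L], v = p[2L], t_d = p[3L],
                            theta = p[4L], E_a = p[5L],
                            mu = init$mu, q = init$q, E_pump = init$E_pump)
  identifiable <- c(
    v_mps = p[2L],
    E_a_eV = p[5L],
    asym_tker_meV = 1000 * (init$E_pump - p[5L]),
    amplitude_eV_nm2 = ion_dipole_potential(1000, p[4L], init$mu, init$q),
    R_at_first_delay_pm = p[1L] + p[2L] * (min(t) - p[3L]))

  structure(list(model = model, estimate = est, se = se, vcov = vc,
                 correlation = corr, identifiable = identifiable,
                 chi2red = chi2red, dof = dof,
                 series = series, sigma_eV = sig,
                 fitted_values = 1000 * tker_evolution(model, t),
                 convergence = list(info = fit$info, message = fit$message,
                                    niter = fit$niter)),
            class = "ion_dipole_fit")
}

#' @export
print.ion_dipole_fit <- function(x, ...) {
  cat("Ion-dipole fit to the mean-TKER evolution\n")
  cat(sprintf("  v = %.3g +/- %.2g m/s,  E_a = %.4g +/- %.2g eV\n",
              x$estimate["v_mps"], x$se["v_mps"],
              x$estimate["E_a_eV"], x$se["E_a_eV"]))
  cat(sprintf("  R_eq = %.4g pm, t_d = %.4g ps, theta = %.3g deg ",
              x$estimate["R_eq_pm"], x$estimate["t_d_ps"],
              x$estimate["theta_deg"]))
  cat("(R_eq and t_d individually degenerate)\n")
  cat(sprintf("  reduced chi-square = %.3g on %d dof\n", x$chi2red, x$dof))
  invisible(x)
}

#' @export
summary.ion_dipole_fit <- function(object, ...) {
  structure(list(coefficients = cbind(Estimate = object$estimate,
                                      `Std. Error` = object$se),
                 correlation = object$correlation,
                 identifiable = object$identifiable,
                 chi2red = object$chi2red, dof = object$dof,
                 convergence = object$convergence),
            class = "summary.ion_dipole_fit")
}

#' @export
print.summary.ion_dipole_fit <- function(x, ...) {
  cat("Ion-dipole fit to the mean-TKER evolution\n\nParameters:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nIdentifiable combinations:\n")
  print(round(x$identifiable, 4))
  cat("\nParameter correlations:\n")
  print(round(x$correlation, 3))
  cat(sprintf("\nReduced chi-square: %.3g on %d dof\n", x$chi2red, x$dof))
  invisible(x)
}

#' @export
coef.ion_dipole_fit <- function(object, ...) object$estimate

#' @export
vcov.ion_dipole_fit <- function(object, ...) object$vcov

#' @export
fitted.ion_dipole_fit <- function(object, ...) object$fitted_values

#' @export
residuals.ion_dipole_fit <- function(object,
                                     type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$series$mean_tker_meV - object$fitted_values
  if (type == "weighted") r / (1000 * object$sigma_eV) else r
}

#' @export
predict.ion_dipole_fit <- function(object, delays = NULL, ...) {
  if (is.null(delays)) return(object$fitted_values)
  1000 * tker_evolution(object$model, delays, mask_before_td = TRUE)
}

#' @export
plot.ion_dipole_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$delay_ps, s$mean_tker_meV, pch = 16,
                 xlab = "pump-probe delay (ps)", ylab = "mean TKER (meV)",
                 ...)
  if (!is.null(s$sigma_meV))
    graphics::arrows(s$delay_ps, s$mean_tker_meV - s$sigma_meV,
                     s$delay_ps, s$mean_tker_meV + s$sigma_meV,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  tt <- seq(min(s$delay_ps), max(s$delay_ps), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "blue3", lty = 2, lwd = 1.5)
  invisible(x)
}
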