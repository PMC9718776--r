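## All interchange is plain text: TSV with explicit headers, '#'-prefixed
## metadata lines, floats at 9 significant digits.
.fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write and read three-channel ion-yield scans
#'
#' One TSV with columns `delay_ps`, `yield`, `sigma`, `channel`; metadata
#' (seed, generating parameters if present) in `#`-prefixed header lines.
#'
#' @param curves Named list of [ion_yield_curve()]s.
#' @param path File path.
#' @return `path` (writer) or the named list of curves (reader),
#'   invisibly/visibly.
#' @export
write_ion_yield_curves <- function(curves, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(curves, "seed")
  truth <- attr(curves, "truth")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  if (!is.null(truth)) {
    writeLines(sprintf("# truth_tau2_fs: %s", .fmt9(truth$scheme$tau2_fs)), con)
    writeLines(sprintf("# truth_tau3_ps: %s", .fmt9(truth$scheme$tau3_ps)), con)
    writeLines(sprintf("# truth_tau4_ps: %s", .fmt9(truth$scheme$tau4_ps)), con)
  }
  writeLines("delay_ps\tyield\tsigma\tchannel", con)
  for (ch in names(curves)) {
    cu <- curves[[ch]]
    writeLines(paste(.fmt9(cu$delay_ps), .fmt9(cu$yield), .fmt9(cu$sigma),
                     ch, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ion_yield_curves
#' @export
read_ion_yield_curves <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("delay_ps", "yield", "sigma", "channel")
  if (!all(need %in% names(df)))
    stop("malformed scan file: need columns ", paste(need, collapse = ", "))
  chans <- unique(df$channel)
  out <- lapply(stats::setNames(nm = chans), function(ch) {
    d <- df[df$channel == ch, ]
    d <- d[order(d$delay_ps), ]
    ion_yield_curve(d$delay_ps, d$yield, d$sigma, ch)
  })
  out
}

#' Write and read a kinetic-energy spectrum
#'
#' TSV with columns `bin_lo_meV`, `bin_hi_meV`, `counts` and metadata
#' header lines `# delay_ps:`, `# m_fragment_u:`, `# m_parent_u:`,
#' `# domain:`.
#'
#' @param spectrum A `ke_spectrum`.
#' @param path File path.
#' @return `path` (writer) or a `ke_spectrum` (reader).
#' @export
write_ke_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(spectrum, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  writeLines(c(sprintf("# delay_ps: %s", .fmt9(spectrum$delay)),
               sprintf("# m_fragment_u: %s", .fmt9(spectrum$m_fragment)),
               sprintf("# m_parent_u: %s", .fmt9(spectrum$m_parent)),
               sprintf("# domain: %s", spectrum$domain),
               "bin_lo_meV\tbin_hi_meV\tcounts"), con)
  n <- length(spectrum$counts)
  writeLines(paste(.fmt9(spectrum$bin_edges[-(n + 1L)]),
                   .fmt9(spectrum$bin_edges[-1L]),
                   .fmt9(spectrum$counts), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_ke_spectrum
#' @export
read_ke_spectrum <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- function(key, cast = as.numeric) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("malformed spectrum file: missing '", key, "'")
    cast(trimws(sub(paste0("^# ", key, ":"), "", ln[1L])))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("bin_lo_meV", "bin_hi_meV", "counts") %in% names(df)))
    stop("malformed spectrum file: wrong columns")
  ke_spectrum(c(df$bin_lo_meV, df$bin_hi_meV[nrow(df)]), df$counts,
              delay = meta("delay_ps"),
              m_fragment = meta("m_fragment_u"),
              m_parent = meta("m_parent_u"),
              domain = meta("domain", cast = as.character))
}

#' Write and read a mean-TKER series
#'
#' TSV with columns `delay_ps`, `mean_tker_meV`, `sigma_meV`.
#'
#' @param series A `tker_series` data.frame.
#' @param path File path.
#' @return `path` (writer) or a `tker_series` (reader).
#' @export
write_tker_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("delay_ps\tmean_tker_meV\tsigma_meV", con)
  s <- if (is.null(series$sigma_meV)) rep(NA_real_, nrow(series)) else
    series$sigma_meV
  writeLines(paste(.fmt9(series$delay_ps), .fmt9(series$mean_tker_meV),
                   .fmt9(s), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_tker_series
#' @export
read_tker_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("delay_ps", "mean_tker_meV") %in% names(df)))
    stop("malformed TKER series file")
  class(df) <- c("tker_series", "data.frame")
  df
}

#' Serialize a ground truth to and from YAML
#'
#' @param truth A [ground_truth()].
#' @param path File path.
#' @return `path` (writer) or a `ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  x <- list(
    scheme = list(tau2_fs = truth$scheme$tau2_fs,
                  tau3_ps = truth$scheme$tau3_ps,
                  tau4_ps = truth$scheme$tau4_ps,
                  gamma21 = truth$scheme$gamma21,
                  delta_omega = truth$scheme$delta_omega),
    pulse = list(rabi_omega0 = truth$pulse$rabi_omega0,
                 tau_irf_fs = truth$pulse$tau_irf_fs),
    coeffs = list(A = truth$coeffs$A, B = truth$coeffs$B, C = truth$coeffs$C),
    osc = unclass(truth$osc),
    dipole = unclass(truth$dipole),
    baseline = as.list(truth$baseline),
    kT_bg = truth$kT_bg,
    mb_form = truth$mb_form)
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  ground_truth(
    scheme = level_scheme(tau2 = x$scheme$tau2_fs, tau3 = x$scheme$tau3_ps,
                          tau4 = x$scheme$tau4_ps,
                          gamma21 = x$scheme$gamma21,
                          delta_omega = x$scheme$delta_omega),
    pulse = excitation_pulse(rabi_omega0 = x$pulse$rabi_omega0,
                             tau_irf = x$pulse$tau_irf_fs),
    coeffs = signal_coefficients(A = unlist(x$coeffs$A),
                                 B = unlist(x$coeffs$B), C = x$coeffs$C),
    osc = do.call(oscillation_params, x$osc),
    dipole = do.call(ion_dipole_model, x$dipole),
    baseline = unlist(x$baseline),
    kT_bg = x$kT_bg, mb_form = x$mb_form)
}

#' Write a flat key-value fit report
#'
#' Serializes a `kinetics_fit` or `ion_dipole_fit` as a flat JSON object
#' (estimates, 1-sigma uncertainties, reduced chi-square, R-squared,
#' degrees of freedom, convergence info).
#'
#' @param fit A `kinetics_fit` or `ion_dipole_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "kinetics_fit")) {
    c(as.list(fit$coefficients),
      stats::setNames(as.list(fit$coefficients_se),
                      paste0(names(fit$coefficients_se), "_se")),
      list(chi2red = fit$chi2red, r_squared = fit$r_squared),
      stats::setNames(as.list(fit$r_squared_channel),
                      paste0("r_squared_", names(fit$r_squared_channel))),
      list(dof = fit$dof, n_data = fit$ndata,
           niter = fit$convergence$niter, lm_info = fit$convergence$info))
  } else if (inherits(fit, "ion_dipole_fit")) {
    c(as.list(fit$estimate),
      stats::setNames(as.list(fit$se), paste0(names(fit$se), "_se")),
      as.list(fit$identifiable),
      list(chi2red = fit$chi2red, dof = fit$dof,
           niter = fit$convergence$niter, lm_info = fit$convergence$info))
  } else stop("unsupported fit object of class ", class(fit)[1L])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
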