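## Standard atomic weights: C 12.011, H 1.008, N 14.007, O 15.999.
## Indole C8H7N = 117.151 u; water 18.015 u; cluster 135.166 u.
.mass_water   <- 18.015
.mass_cluster <- 135.166

#' Binned kinetic-energy spectrum at one pump-probe delay
#'
#' @param bin_edges Bin edges in meV, strictly increasing, non-negative.
#' @param counts Per-bin intensity, length `length(bin_edges) - 1` (may be
#'   negative after background subtraction).
#' @param delay Pump-probe delay in ps (negative delays sample the static
#'   background).
#' @param m_fragment,m_parent Fragment and parent masses in u.
#' @param domain `"ke"` for projected fragment kinetic energy, `"tker"`
#'   after the total-kinetic-energy-release transform.
#' @return An object of class `ke_spectrum`.
#' @export
ke_spectrum <- function(bin_edges, counts, delay,
                        m_fragment = .mass_water, m_parent = .mass_cluster,
                        domain = c("ke", "tker")) {
  domain <- match.arg(domain)
  if (any(diff(bin_edges) <= 0) || any(bin_edges < 0))
    stop("'bin_edges' must be strictly increasing and non-negative")
  if (length(counts) != length(bin_edges) - 1L)
    stop("'counts' must have one entry per bin")
  if (any(!is.finite(counts))) stop("'counts' must be finite")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts), delay = delay,
                 m_fragment = m_fragment, m_parent = m_parent,
                 domain = domain),
            class = "ke_spectrum")
}

#' @export
print.ke_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum at delay %.4g ps: %d bins, %.4g .. %.4g meV\n",
              toupper(x$domain), x$delay, length(x$counts),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Total kinetic energy release from one fragment's kinetic energy
#'
#' For a two-body dissociation with momentum conservation, the total
#' kinetic energy release follows from the measured fragment kinetic
#' energy as `E_K * m_parent / (m_parent - m_fragment)` (the co-fragment
#' carries `m_parent - m_fragment`). Linear and strictly increasing in
#' `E_K`.
#'
#' @param fragment_ke Fragment kinetic energy (any energy unit).
#' @param m_fragment,m_parent Fragment and parent masses, u.
#' @return TKER in the same unit as `fragment_ke`.
#' @examples
#' ke_to_tker(100, 18.015, 135.166)  # 115.38 meV
#' @export
ke_to_tker <- function(fragment_ke, m_fragment = .mass_water,
                       m_parent = .mass_cluster) {
  if (m_fragment <= 0 || m_parent <= 0) stop("masses must be positive")
  if (m_parent <= m_fragment)
    stop("'m_parent' must exceed 'm_fragment' (co-fragment mass positive)")
  fragment_ke * m_parent / (m_parent - m_fragment)
}

#' Transform a fragment-KE spectrum to the TKER domain
#'
#' Rescales the energy axis by [ke_to_tker()]; counts are unchanged
#' (per-bin counts, not densities).
#'
#' @param spectrum A `ke_spectrum` with `domain == "ke"`.
#' @return The spectrum with TKER bin edges and `domain == "tker"`.
#' @export
spectrum_to_tker <- function(spectrum) {
  stopifnot(inherits(spectrum, "ke_spectrum"))
  if (spectrum$domain == "tker") return(spectrum)
  spectrum$bin_edges <- ke_to_tker(spectrum$bin_edges, spectrum$m_fragment,
                                   spectrum$m_parent)
  spectrum$domain <- "tker"
  spectrum
}

#' Subtract the mean negative-delay background from a spectrum set
#'
#' The water-ion signal at negative delays is delay-independent (it stems
#' from ionization-induced dissociation of water dimers, not from the
#' UV-triggered dynamics). The per-bin mean over all negative-delay
#' spectra is taken as the static background and subtracted from every
#' spectrum.
#'
#' @param spectra List of `ke_spectrum` objects with identical binning,
#'   at least one with `delay < 0`.
#' @return List with `spectra` (background-subtracted, same order) and
#'   `background` (a `ke_spectrum` labelled with delay `NA`).
#' @export
subtract_negative_delay_background <- function(spectra) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "ke_spectrum")))
  edges <- spectra[[1L]]$bin_edges
  for (sp in spectra)
    if (length(sp$bin_edges) != length(edges) ||
        any(abs(sp$bin_edges - edges) > 1e-9))
      stop("all spectra must share identical binning")
  neg <- vapply(spectra, function(sp) sp$delay < 0, TRUE)
  if (!any(neg)) stop("need at least one negative-delay spectrum")
  bg_counts <- rowMeans(vapply(spectra[neg], function(sp) sp$counts,
                               numeric(length(edges) - 1L)))
  bg <- spectra[[which(neg)[1L]]]
  bg$counts <- bg_counts
  bg$delay <- NA_real_
  out <- lapply(spectra, function(sp) { sp$counts <- sp$counts - bg_counts; sp })
  list(spectra = out, background = bg)
}

## analytic mean of the chosen Maxwell-Boltzmann form
.mb_mean <- function(kT, form) switch(form, energy3d = 1.5 * kT,
                                      projected = kT)

## MB density shape (unnormalized) on energy E >= 0
.mb_shape <- function(E, kT, form) switch(form,
  energy3d = sqrt(pmax(E, 0)) * exp(-E / kT),
  projected = exp(-E / kT))

#' Draw energies from a Maxwell-Boltzmann distribution
#'
#' `"energy3d"` is the speed distribution in energy form,
#' \eqn{P(E) \propto \sqrt{E} e^{-E/kT}} (a Gamma(3/2, kT); mean 3kT/2);
#' `"projected"` is the 2D-projected form \eqn{P(E) \propto e^{-E/kT}}
#' (Exponential; mean kT).
#'
#' @param n Number of samples.
#' @param kT Characteristic energy (any unit; output is in the same unit).
#' @param form `"energy3d"` (default) or `"projected"`.
#' @return Numeric vector of energies.
#' @export
rmaxboltz <- function(n, kT, form = c("energy3d", "projected")) {
  form <- match.arg(form)
  switch(form,
         energy3d = stats::rgamma(n, shape = 1.5, scale = kT),
         projected = stats::rexp(n, rate = 1 / kT))
}

#' Fit a Maxwell-Boltzmann distribution to a kinetic-energy spectrum
#'
#' Weighted least-squares fit of `amplitude * P(E; kT)` to the per-bin
#' counts at the bin centres, with `P` the chosen Maxwell-Boltzmann form.
#' The reported mean is the analytic mean of the fitted form (3kT/2 for
#' `"energy3d"`, kT for `"projected"`), not the histogram mean.
#'
#' @param spectrum A background-subtracted `ke_spectrum` (KE or TKER
#'   domain) with positive total signal.
#' @param form Maxwell-Boltzmann form, see [rmaxboltz()].
#' @param sigma Optional per-bin 1-sigma weights; default uniform.
#' @return An object of class `mb_fit`: list with `kT`, `kT_se`,
#'   `amplitude`, `mean`, `mean_se` (all energies in the spectrum's unit,
#'   meV), `form`, `rss`, `niter`.
#' @export
fit_maxwell_boltzmann <- function(spectrum, form = c("energy3d", "projected"),
                                  sigma = NULL) {
  form <- match.arg(form)
  stopifnot(inherits(spectrum, "ke_spectrum"))
  E <- (spectrum$bin_edges[-1L] + spectrum$bin_edges[-length(spectrum$bin_edges)]) / 2
  y <- spectrum$counts
  if (sum(y) <= 0) stop("insufficient signal: non-positive total counts")
  w <- if (is.null(sigma)) rep(1, length(y)) else 1 / sigma
  pos <- y > 0
  kT0 <- sum(E[pos] * y[pos]) / sum(y[pos]) / switch(form, energy3d = 1.5,
                                                     projected = 1)
  kT0 <- max(kT0, 1e-3)
  amp0 <- max(y) / max(.mb_shape(E, kT0, form))
  resid_fn <- function(p) {
    kT <- exp(p[1L])
    w * (y - p[2L] * .mb_shape(E, kT, form))
  }
  fit <- minpack.lm::nls.lm(c(log(kT0), amp0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  kT <- exp(fit$par[1L])
  dof <- length(y) - 2L
  s2 <- sum(fit$fvec^2) / max(dof, 1L)
  kT_se <- tryCatch({
    vc <- solve(fit$hessian) * s2
    kT * sqrt(vc[1L, 1L])          # delta method from log kT
  }, error = function(e) NA_real_)
  mfac <- switch(form, energy3d = 1.5, projected = 1)
  structure(list(kT = kT, kT_se = kT_se, amplitude = fit$par[2L],
                 mean = mfac * kT, mean_se = mfac * kT_se, form = form,
                 rss = sum(fit$fvec^2), niter = fit$niter),
            class = "mb_fit")
}

#' @export
print.mb_fit <- function(x, ...) {
  cat(sprintf("Maxwell-Boltzmann fit (%s): kT = %.4g +/- %.2g meV, ",
              x$form, x$kT, x$kT_se))
  cat(sprintf("mean = %.4g meV\n", x$mean))
  invisible(x)
}

#' Mean-TKER series from delay-resolved spectra
#'
#' Pipeline helper: transforms each spectrum to the TKER domain, subtracts
#' the negative-delay background, fits the Maxwell-Boltzmann form to every
#' spectrum with `delay > min_delay`, and collects the analytic means.
#'
#' @param spectra List of `ke_spectrum` objects (KE domain) including
#'   negative delays.
#' @param min_delay Only delays above this (ps) are fitted; default 65 ps,
#'   where the distributions are Maxwell-Boltzmann-like.
#' @param form Maxwell-Boltzmann form.
#' @return A data.frame with columns `delay_ps`, `mean_tker_meV`,
#'   `sigma_meV`, `kT_meV` (class `tker_series`).
#' @export
mean_tker_series <- function(spectra, min_delay = 65,
                             form = c("energy3d", "projected")) {
  form <- match.arg(form)
  tker <- lapply(spectra, spectrum_to_tker)
  sub <- subtract_negative_delay_background(tker)
  keep <- Filter(function(sp) !is.na(sp$delay) && sp$delay > min_delay,
                 sub$spectra)
  if (!length(keep)) stop("no spectra beyond 'min_delay'")
  rows <- lapply(keep, function(sp) {
    f <- fit_maxwell_boltzmann(sp, form = form)
    data.frame(delay_ps = sp$delay, mean_tker_meV = f$mean,
               sigma_meV = f$mean_se, kT_meV = f$kT)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delay_ps), ]
  rownames(out) <- NULL
  class(out) <- c("tker_series", "data.frame")
  out
}
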