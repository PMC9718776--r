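## Known RunConfig keys and defaults. Unknown keys are rejected so typos
## fail loudly instead of silently using defaults.
.config_defaults <- function() list(
  seed = 1L,
  outdir = ".",
  scan_file = "ion_yields.tsv",
  osc_file = "oscillation_scan.tsv",
  spectra_dir = "spectra",
  truth_file = "truth.yaml",
  ## model constants
  tau_irf_fs = 381, probe_fwhm_fs = 70, rabi_omega0 = 3.4,
  mu_D = 1.96, q_e = 1, E_pump_eV = 4.61,
  m_fragment_u = 18.015, m_parent_u = 135.166,
  ## generating parameters (simulate) / start values (fit)
  tau2_fs = 445, tau3_ps = 13, tau4_ps = 96,
  R_eq_pm = 490, v_mps = 12, t_d_ps = 51, theta_deg = 38, E_a_eV = 4.57,
  kT_bg_meV = 60, mb_form = "energy3d",
  ## scan / noise
  noise_model = "gaussian", noise_level = 0.03,
  samples_per_delay = 20000, dyn_fraction = 0.8,
  ## fit options
  baseline_mode = "fit", baseline_before = -0.5,
  max_iter = 100, mb_min_delay = 65
)

#' Build or read a run configuration
#'
#' `run_config()` fills defaults and validates; `read_run_config()` reads a
#' YAML file and validates. Unknown keys are an error.
#'
#' @param ... Named overrides of the defaults (see
#'   `names(ppkin:::.config_defaults())`).
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  cfg <- .config_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

.truth_from_config <- function(cfg) {
  ground_truth(
    scheme = level_scheme(tau2 = cfg$tau2_fs, tau3 = cfg$tau3_ps,
                          tau4 = cfg$tau4_ps),
    pulse = excitation_pulse(rabi_omega0 = cfg$rabi_omega0,
                             tau_irf = cfg$tau_irf_fs),
    dipole = ion_dipole_model(R_eq = cfg$R_eq_pm, v = cfg$v_mps,
                              t_d = cfg$t_d_ps, theta = cfg$theta_deg,
                              E_a = cfg$E_a_eV, mu = cfg$mu_D, q = cfg$q_e,
                              E_pump = cfg$E_pump_eV),
    kT_bg = cfg$kT_bg_meV, mb_form = cfg$mb_form)
}

#' Run the simulation pipeline from a configuration
#'
#' Writes a seeded synthetic three-channel delay scan, a set of
#' delay-resolved kinetic-energy spectra, and the ground-truth YAML into
#' `config$outdir`.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  truth <- .truth_from_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  scan <- generate_ion_yield_scan(truth,
                                  paper_scan_design(cfg$noise_model,
                                                    cfg$noise_level),
                                  seed = cfg$seed)
  scan_path <- file.path(cfg$outdir, cfg$scan_file)
  write_ion_yield_curves(scan, scan_path)
  ## dedicated high-resolution transient for the oscillation-parameter fit
  ## (the coarse long-delay design undersamples the 1.67 ps modulation)
  hr <- scan_design(seq(100, 133.4, by = 0.1),
                    noise_model = cfg$noise_model,
                    noise_level = cfg$noise_level)
  hr_scan <- generate_ion_yield_scan(truth, hr, seed = cfg$seed + 1L)
  osc_path <- file.path(cfg$outdir, cfg$osc_file)
  write_ion_yield_curves(hr_scan["fragment"], osc_path)
  spectra <- generate_ke_spectra(truth,
                                 samples_per_delay = cfg$samples_per_delay,
                                 dyn_fraction = cfg$dyn_fraction,
                                 seed = cfg$seed)
  spdir <- file.path(cfg$outdir, cfg$spectra_dir)
  dir.create(spdir, recursive = TRUE, showWarnings = FALSE)
  sp_paths <- vapply(seq_along(spectra), function(i) {
    p <- file.path(spdir, sprintf("spectrum_%03d.tsv", i))
    sp <- spectra[[i]]
    attr(sp, "seed") <- attr(spectra, "seed")
    write_ke_spectrum(sp, p)
    p
  }, "")
  truth_path <- file.path(cfg$outdir, cfg$truth_file)
  write_ground_truth(truth, truth_path)
  invisible(c(scan = scan_path, oscillation = osc_path,
              truth = truth_path, sp_paths))
}

#' Run the global kinetics fit from a configuration
#'
#' Reads the scan TSV, fits the five-level reaction model and writes a
#' flat JSON report (`kinetics_fit.json`) next to it.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The `kinetics_fit`, invisibly.
#' @export
run_fit_kinetics <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  curves <- read_ion_yield_curves(file.path(cfg$outdir, cfg$scan_file))
  fit <- fit_reaction_model(
    curves,
    scheme_init = level_scheme(tau2 = cfg$tau2_fs, tau3 = cfg$tau3_ps,
                               tau4 = cfg$tau4_ps),
    pulse = excitation_pulse(rabi_omega0 = cfg$rabi_omega0,
                             tau_irf = cfg$tau_irf_fs),
    probe_fwhm = cfg$probe_fwhm_fs,
    baseline = cfg$baseline_mode,
    baseline_before = cfg$baseline_before,
    max_iter = cfg$max_iter)
  write_fit_report(fit, file.path(cfg$outdir, "kinetics_fit.json"))
  invisible(fit)
}

#' Run the oscillation-parameter fit from a configuration
#'
#' Reads the high-resolution oscillation transient written by
#' [run_simulate()] and fits the modulation parameters.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @param channel Channel to use.
#' @return The [fit_oscillation()] result, invisibly.
#' @export
run_fit_oscillation <- function(config = run_config(), channel = "fragment") {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  curves <- read_ion_yield_curves(file.path(cfg$outdir, cfg$osc_file))
  if (!channel %in% names(curves)) stop("channel '", channel, "' not in scan")
  res <- fit_oscillation(curves[[channel]], envelope = "quadratic")
  jsonlite::write_json(res[c("a", "b", "omega", "phi", "rss")],
                       file.path(cfg$outdir, "oscillation_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Run the TKER analysis from a configuration
#'
#' Reads the spectra directory, builds the mean-TKER series
#' (TKER transform, background subtraction, per-delay Maxwell-Boltzmann
#' fits) and fits the ion-dipole model; writes `mean_tker.tsv` and
#' `tker_fit.json`.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The `ion_dipole_fit`, invisibly.
#' @export
run_fit_tker <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  spdir <- file.path(cfg$outdir, cfg$spectra_dir)
  paths <- sort(list.files(spdir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(paths)) stop("no spectra found in ", spdir)
  spectra <- lapply(paths, read_ke_spectrum)
  series <- mean_tker_series(spectra, min_delay = cfg$mb_min_delay,
                             form = cfg$mb_form)
  write_tker_series(series, file.path(cfg$outdir, "mean_tker.tsv"))
  init <- ion_dipole_model(R_eq = cfg$R_eq_pm, v = cfg$v_mps,
                           t_d = cfg$t_d_ps, theta = cfg$theta_deg,
                           E_a = cfg$E_a_eV, mu = cfg$mu_D, q = cfg$q_e,
                           E_pump = cfg$E_pump_eV)
  fit <- fit_ion_dipole(series, init = init)
  write_fit_report(fit, file.path(cfg$outdir, "tker_fit.json"))
  invisible(fit)
}
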