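---
title: "Modelling UV-pump/NIR-probe dynamics of a singly microsolvated chromophore"
author: "ppkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UV-pump/NIR-probe dynamics of a singly microsolvated chromophore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppkin)
```

## The physical problem

ppkin models a femtosecond pump-probe experiment on a chromophore bound to a
single water molecule (microsolvation). A UV pulse excites the aggregate; a
delayed near-infrared pulse ionizes it, and delay-dependent ion yields are
recorded for three mass channels: the intact cluster cation ("parent"), the
bare chromophore cation ("fragment"), and the water cation ("water"). Two
analyses are implemented:

1. a **five-level Maxwell-Bloch reaction model** fitted globally to the three
   transients, yielding the excited-state lifetimes along the relaxation
   cascade, and
2. a **kinetic-energy-release (TKER) analysis** of the water-cation channel,
   in which delay-resolved kinetic-energy spectra are background-subtracted,
   fitted with Maxwell-Boltzmann distributions, and the delay evolution of
   the mean TKER is described by a classical ion-dipole separation model.

Because the package is developed and tested without access to the
experimental data, a first-class synthetic-data generator reproduces the
statistical structure the analysis assumes; every estimator is validated by
parameter recovery against known ground truth.

## The five-level reaction model

The photophysics is a sequential cascade

$$ S_0\,(1) \xrightarrow{\,UV\,} \pi\pi^*\,(2) \xrightarrow{\tau_2}
   \pi\sigma^*\,(3) \xrightarrow{\tau_3} S_0^{hot}\,(4) \xrightarrow{\tau_4}
   \text{products}\,(5), $$

with $\Gamma_{ii} = 1/\tau_i$. States 1 and 2 are coupled coherently by the
pump field; the equations of motion for the populations $\rho_{ii}$ and the
coherence $\rho_{21}$ are

$$
\begin{aligned}
\dot\rho_{11} &= \tfrac{i}{2}\Omega_0 g(t) (\rho_{12}-\rho_{21}), &
\dot\rho_{22} &= -\tfrac{i}{2}\Omega_0 g(t) (\rho_{12}-\rho_{21})
                 - \Gamma_{22}\rho_{22},\\
\dot\rho_{21} &= -\tfrac{i}{2}\Omega_0 g(t)(\rho_{11}-\rho_{22})
                 - (\Gamma_{21} - i\Delta\omega)\rho_{21}, &
\dot\rho_{33} &= \Gamma_{22}\rho_{22} - \Gamma_{33}\rho_{33},
\end{aligned}
$$

and analogously down the chain, with the peak-normalized Gaussian envelope
$g(t) = \exp(-t^2/2\tau_{IRF}^2)$ standing in for the instrument response.
Assumptions inherited from the underlying physics: resonant excitation
($\Delta\omega = 0$), coherence decay $\Gamma_{21} = \Gamma_{22}/2$, no
distinction between the two low-lying $\pi\pi^*$ states, strictly sequential
population flow, and all population initially in state 1.

Key parameters and defaults (all overridable):

| parameter | meaning | default |
|---|---|---|
| $\Omega_0$ | peak Rabi frequency | 3.4 rad/ps |
| $\tau_{IRF}$ | IRF width parameter of $g$ | 381 fs |
| $\tau_2,\tau_3,\tau_4$ | cascade lifetimes | 445 fs, 13 ps, 96 ps |
| probe FWHM | intensity envelope of the ionizing pulse | 70 fs |

`estimate_rabi_frequency()` implements the textbook convention
$\Omega_0 = \mu_{12} E_0/\hbar$ with $E_0 = \sqrt{2I/\epsilon_0 c}$; for the
nominal pulse parameters ($I = 2\cdot10^9$ W/cm$^2$, $\mu_{12} = 15$ e pm) it
gives $\approx 2.8$ rad/ps rather than the 3.4 rad/ps adopted as the default.
Field-amplitude conventions differ between authors by factors of order one,
so the estimator is advisory only and $\Omega_0$ is always taken as a direct
input.

Similarly, $\tau_{IRF}$ is interpreted literally as the width parameter of
the Gaussian as written (not as a FWHM-derived quantity): with that reading,
$g(0)=1$, and the adopted $\Omega_0$ is the value that pairs with that
normalization.

### Numerical integration

The system is integrated over 7 real components (five populations plus
Re/Im $\rho_{21}$; $\rho_{12}$ is the conjugate by construction, which
enforces Hermiticity structurally) with `lsoda` and a compiled C right-hand
side at `rtol = atol = 1e-9`. The system is mildly stiff — lifetimes span
445 fs to 96 ps — and the tight tolerances keep the population sum conserved
to better than $10^{-8}$ (the RHS conserves it identically). Integration
starts at $-5$ ps ($\approx 13\,\tau_{IRF}$, where $g < 10^{-37}$), so the
$\rho_{11}(-\infty) = 1$ initial condition holds to machine precision; a
start time with $g(t_{start}) > 10^{-6}$ is refused. The dense output grid
uses 1 fs steps for $|t| < 10$ ps (resolving the 70 fs probe kernel and the
445 fs decay) and 50 fs steps beyond, stitched exactly; 140 ps scans remain
tractable.

The closed-form Bateman solution of the post-pulse cascade — including the
analytic $t e^{-\Gamma t}$ limiting forms for pairwise-equal rates (rates
closer than a relative $10^{-8}$ are treated as equal) — serves as an
independent oracle: the test suite checks the integrated post-pulse dynamics
against it to $10^{-6}$.

### Probe convolution

The measured signals reflect populations convolved with the probe intensity
envelope, an area-normalized Gaussian of 70 fs FWHM. ppkin computes this
convolution **exactly for the piecewise-linear interpolant** of the trace:
each linear segment contributes a closed-form term in the normal cdf/pdf,
windowed at $\pm10\sigma$. This reproduces constant segments exactly and
meets the $10^{-6}$ step-response criterion that a discrete quadrature of
practical resolution cannot.

### The ion-signal model and the global fit

$$
I_{parent}(t) = p^{osc}_{parent}(t)\sum_{i=2}^4 A_i\rho'_{ii}(t),\qquad
I_{fragment}(t) = p^{osc}_{fragment}(t)\sum_{i=2}^5 B_i\rho'_{ii}(t),\qquad
I_{water}(t) = C\,\rho'_{55}(t),
$$

with $p^{osc}_j(t) = a_j + b_j\cos(\omega t + \phi)$ describing an undamped
vibrational-wavepacket modulation of the ionization probability (defaults
$a = 1.04, b = 0.14$ parent; $a = 0.92, b = 0.11$ fragment; $\phi = 1.77$).
The frequency is stored as the angular frequency $\omega = 3.77$ rad/ps so
that the period is $2\pi/\omega = 1.67$ ps and the corresponding vibrational
spacing is 20 cm$^{-1}$; these parameters are determined once from a
high-resolution transient (`fit_oscillation()`) and then held fixed in the
global fit.

`fit_reaction_model()` fits $(\tau_2,\tau_3,\tau_4, A_{2..4}, B_{2..5}, C)$
jointly across the three channels by Levenberg-Marquardt on the
$\sigma$-weighted residuals (a reduced-$\chi^2$ objective), re-integrating
the Maxwell-Bloch equations at every iteration. Design choices:

* **Log-space lifetimes.** The $\tau$'s are fitted as logarithms, enforcing
  positivity and balancing steps across three decades of timescales;
  coefficients are bounded below by zero.
* **Baseline handling.** All channels carry a constant ionization background
  at negative delays. The default (`baseline = "fit"`) adds one free
  constant per channel, because with a 381 fs IRF the model is *not* zero at
  the earliest measured delays ($-1.5$ to $-0.7$ ps), so estimating the
  background as the negative-delay mean both biases the fit and injects a
  correlated offset error; fitting it restores exact self-consistency on
  noiseless data and propagates the offset uncertainty into the lifetimes.
  The subtract-the-mean estimator is retained (`baseline = "subtract"`) but
  is applied to data *and model* alike, which removes its bias.
* **Non-uniform delay grids are first-class.** The model is evaluated by
  exact convolution at the measured delays; the data are never resampled.
* **Weights** default to the per-point experimental $\sigma$; with
  correctly specified noise the reduced $\chi^2$ is $\approx 1$.
* **Uncertainties** are $1\sigma$ values from the Levenberg-Marquardt
  covariance scaled by the reduced $\chi^2$ (lifetimes by the delta method
  from log-space). $R^2$ is reported jointly and per channel, since either
  convention is found in practice.

## The TKER analysis

For two-body dissociation, momentum conservation converts the measured
water-fragment kinetic energy into the total release,
$\mathrm{TKER} = E^K_{frag}\, m_{parent}/(m_{parent}-m_{frag})$, with
standard atomic weights ($m_{frag} = 18.015$ u, $m_{parent} = 135.166$ u,
configurable for isotopologues). The delay-independent contribution from
water-dimer dissociation is removed by subtracting the per-bin mean of all
negative-delay spectra; the subtraction round-trips exactly.

Spectra at long delays are fitted with a Maxwell-Boltzmann form. The
projected-versus-3D ambiguity of 1D kinetic-energy histograms is handled by
implementing both: `"energy3d"`, $P(E)\propto\sqrt{E}e^{-E/kT}$ with
analytic mean $\tfrac32 kT$ (the default), and `"projected"`,
$P(E)\propto e^{-E/kT}$ with mean $kT$. The reported mean TKER is always the
analytic mean of the fitted form, never the histogram mean, which is robust
to binning and truncation.

The delay evolution of the mean TKER is modelled classically: after
statistical unimolecular dissociation at delay $t_d$, the fragments separate
linearly, $R(t) = R_{eq} + v(t-t_d)$, and the water cation created by the
probe experiences the charge-dipole repulsion
$V = q\mu\cos\theta / 4\pi\epsilon_0 R^2$ (ion-induced-dipole and
dipole-dipole terms neglected), so

$$ \mathrm{TKER}(t) = E_{pump} + V(t) - E_a, $$

approaching $E_{pump}-E_a$ from above. With the default parameter set
($R_{eq} = 490$ pm, $v = 12$ m/s, $t_d = 51$ ps, $\theta = 38^\circ$,
$E_a = 4.57$ eV, fixed $\mu = 1.96$ D, $q = 1$ e, $E_{pump} = 4.61$ eV) the
contact potential is 0.193 eV and the asymptote 40 meV. The model is
undefined before $t_d$ and evaluation there is refused (or masked to `NA` on
request) rather than extrapolated.

**Identifiability.** Because $R(t)$ is linear in $t$, only the combinations
$(R_{eq}-v t_d,\; v,\; q\mu\cos\theta,\; E_{pump}-E_a)$ enter the model:
$R_{eq}$ and $t_d$ are exactly degenerate along $dR_{eq} = v\,dt_d$, and
$\theta$ is constrained only through the amplitude. `fit_ion_dipole()`
nevertheless performs the conventional five-parameter fit (with $t_d$
bounded below the first measured delay and a pseudo-inverse fallback for the
singular covariance) and `summary()` reports the parameter correlations plus
the identifiable combinations, so the degeneracy is visible rather than
hidden. The physically interesting quantities — $v$ and $E_a$ — are
identifiable and recover well.

## The synthetic-data generator

`generate_ion_yield_scan()` evaluates the full ion-signal model on the
published scan design (417 fs steps over $-1.535\ldots6.805$ ps, one 834 fs
step, 1.668 ps steps beyond — extended here to 139.4 ps to cover the slow
dissociation — and $-5.705\ldots140.245$ ps in 4.17 ps steps for the water
channel), adds constant per-channel baselines, and applies noise. The
defaults define the study conditions:

* **Noise**: Gaussian, $\sigma$ = 3% of the channel's peak model value,
  attached per point; a Poisson counting mode (shots-per-point ~8000 indole
  channels, ~41000 water) is available.
* **Channel coefficients** $A = (1.0, 0.55, 0.30)$,
  $B = (0.25, 0.45, 0.65, 0.80)$, $C = 0.5$ and baselines
  $(0.10, 0.15, 0.05)$: chosen once to reproduce the qualitative channel
  shapes of the experiment (parent: fast rise, then fast and slow decay;
  fragment: fast rise delayed relative to the parent, then slow growth;
  water: slow growth only). The absolute scale is arbitrary.
* **Spectra**: each delay draws 20 000 energies from the static background
  (Maxwell-Boltzmann at $kT_{bg} = 60$ meV — a deliberately arbitrary,
  documented value, since the analysis must work for any background shape)
  plus, past $t_d$, 0.8 times as many from a Maxwell-Boltzmann component
  whose analytic mean equals the ion-dipole prediction; energies are
  converted to the fragment-KE frame and histogrammed (0–400 meV, 5 meV
  bins), so bin noise is naturally Poissonian.

Everything is deterministic given (truth, design, seed), and generated files
embed the seed and generating parameters.

What the generator does **not** emulate: detector-image formation and Abel
projection (spectra are generated directly in energy space), species
contamination beyond the static background term, slow drifts or overlap
instabilities, and shot-to-shot correlations. Passing recovery tests
therefore demonstrate the correctness and calibration of the estimators
under the stated noise model, not robustness to every systematic present in
real data.

## Recovery behaviour and known limitations

With the defaults above, noiseless scans are recovered to better than
$10^{-4}$ relative in all three lifetimes, and the reduced $\chi^2$ over
replicates is consistent with 1. At the 3% noise level the replicate-to-seed
scatter of the recovered lifetimes, in agreement with the fits' own reported
covariance, is roughly 120 fs for $\tau_2$, 1.5 ps for $\tau_3$ and 6 ps for
$\tau_4$: the medians across 20 replicates sit well within the nominal
uncertainties of the generating values, while individual replicates scatter
beyond the narrowest of those windows for $\tau_2$. How sharply $\tau_2$ is
determined depends strongly on the (experimentally unpublished) channel
coefficients through the contrast of the fast decay component; the
registered defaults are a conservative choice in that respect.

Test and example problem sizes (20 replicates for recovery studies, 20 000
samples per synthetic spectrum, 101 + 101 + 36-point scans) are chosen so
the whole suite runs in a couple of minutes on a single core while leaving
the Monte-Carlo assertions well-powered.

Other limitations, by construction: no branching or non-sequential kinetics,
a single coherence pair (no multi-state coherences), no fitting of the IRF
itself, no treatment of the ionization photon-order physics beyond its
imprint in the channel coefficients, no Abel inversion (inputs are 1D
projected-KE histograms), and no hydronium-channel modelling.

## A minimal end-to-end run

```{r example, eval = FALSE}
truth <- ground_truth()
scan <- generate_ion_yield_scan(truth, paper_scan_design(), seed = 1)
fit <- fit_reaction_model(scan)
summary(fit)

spectra <- generate_ke_spectra(truth, seed = 1)
series <- mean_tker_series(spectra)
idfit <- fit_ion_dipole(series)
summary(idfit)
```

The same pipeline is available from the shell through the thin front-end
`inst/cli/ppkin.R` (subcommands `simulate`, `fit-kinetics`,
`fit-oscillation`, `fit-tker`) and from R through `run_simulate()`,
`run_fit_kinetics()`, `run_fit_oscillation()` and `run_fit_tker()`, all
driven by a validated YAML configuration (`run_config()`).
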