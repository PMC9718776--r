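# ppkin

Global analysis of UV-pump/NIR-probe ion-yield transients and fragment
kinetic-energy-release (TKER) spectra for microsolvated chromophores —
specifically the photoinduced relaxation and dissociation of a
chromophore·H₂O cluster observed through three mass channels
(cluster⁺, chromophore⁺, H₂O⁺).

## What it computes

**Reaction kinetics.** The package integrates the five-level Maxwell-Bloch
equations for the sequential scheme

    S0 (1) --UV--> ππ* (2) --τ2--> πσ* (3) --τ3--> hot S0 (4) --τ4--> products (5)

with Γᵢᵢ = 1/τᵢ, a coherent 1↔2 coupling Ω₀·g(t), and the peak-normalized
Gaussian IRF envelope g(t) = exp(−t²/2τ²_IRF). Ion yields are modelled as
oscillation-modulated linear combinations of the probe-convolved populations,

    I_parent   = p_osc(t) Σ_{i=2..4} A_i ρ'_ii,
    I_fragment = p_osc(t) Σ_{i=2..5} B_i ρ'_ii,
    I_water    = C ρ'_55,

and `fit_reaction_model()` fits (τ2, τ3, τ4, A, B, C) jointly to the three
channels by Levenberg-Marquardt on a reduced-χ² objective, returning a
classed fit object with `print`, `summary`, `coef`, `vcov`, `predict`,
`residuals` and `plot` methods.

**TKER analysis.** `ke_to_tker()` converts fragment kinetic energy to total
release by momentum conservation; `subtract_negative_delay_background()`
removes the static water-dimer contribution; `fit_maxwell_boltzmann()` fits
P(E) ∝ √E·e^(−E/kT) (or the projected e^(−E/kT) variant) and reports the
analytic mean; `fit_ion_dipole()` fits the classical charge-dipole
separation model

    TKER(t) = E_pump − E_a + q μ cosθ / (4π ε0 [R_eq + v (t − t_d)]²)

to the delay evolution of the mean TKER.

**Synthetic data.** `ground_truth()`, `paper_scan_design()`,
`generate_ion_yield_scan()`, `generate_ke_spectra()` and
`generate_mean_tker()` produce fully seeded datasets with the statistical
structure the analysis assumes, so every estimator is validated by parameter
recovery.

## Worked example

```r
library(ppkin)

truth <- ground_truth()                  # nominal lifetimes 445 fs / 13 ps / 96 ps
scan  <- generate_ion_yield_scan(truth, paper_scan_design(), seed = 1)
fit   <- fit_reaction_model(scan)
fit
#> Global five-level reaction-model fit
#>   tau2 = 345 +/- 102 fs
#>   tau3 = 11.7 +/- 1.3 ps
#>   tau4 = 101 +/- 6 ps
#>   reduced chi-square = 0.915,  R^2 = 0.9945  (238 points, 224 dof)

ser <- generate_mean_tker(truth, seed = 1)   # mean TKER vs delay, 5% noise
fit_ion_dipole(ser)
#> Ion-dipole fit to the mean-TKER evolution
#>   v = 12.4 +/- 1.4 m/s,  E_a = 4.568 +/- 0.0039 eV
#>   R_eq = 463.9 pm, t_d = 47.17 ps, theta = 32.7 deg (R_eq and t_d individually degenerate)
#>   reduced chi-square = 0.935 on 17 dof
```

The lifetimes recovered from a single noisy replicate scatter around the
generating values within the quoted 1σ uncertainties; the reduced χ² near 1
confirms the weights match the generating noise. In the ion-dipole fit the
separation speed v and asymptotic internal energy E_a are the identifiable
physical quantities; R_eq and t_d trade off exactly against each other (see
`summary()` for the correlation matrix and the identifiable combinations).

A shell front-end wraps the same pipeline:

```sh
Rscript inst/cli/ppkin.R simulate     --seed 1 --outdir out
Rscript inst/cli/ppkin.R fit-kinetics --outdir out
Rscript inst/cli/ppkin.R fit-tker     --outdir out
```

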