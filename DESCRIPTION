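Package: ppkin
Title: Pump-Probe Kinetics of Microsolvated Chromophores: Five-Level
    Maxwell-Bloch Fitting and Kinetic-Energy-Release Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global analysis of UV-pump/NIR-probe ion-yield transients with a
    five-level Maxwell-Bloch reaction model (coherent two-level excitation by
    a Gaussian instrument-response envelope feeding a sequential decay
    cascade), including probe-pulse convolution, fixed wavepacket-oscillation
    modulation, and joint Levenberg-Marquardt fitting of time constants and
    channel coefficients across mass channels. Companion analysis of
    delay-resolved fragment kinetic-energy spectra: total kinetic energy
    release (TKER) transform, negative-delay background subtraction,
    Maxwell-Boltzmann fits, and a classical ion-dipole model for the delay
    evolution of the mean TKER. Includes a seeded synthetic-data generator
    for parameter-recovery studies and plain-text TSV/YAML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
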