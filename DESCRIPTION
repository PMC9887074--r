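Package: pfgdiff
Title: Pulsed-Field-Gradient Diffusion NMR: Signal Models, Simulation and
    Validation Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pulsed-field-gradient (PFG) diffusion-weighted
    NMR attenuation signals. Provides closed-form and quadrature-based
    attenuation models for Gaussian stationary-increment diffusion (the full
    Stejskal-Tanner expression with a finite velocity-correlation time and its
    extension to anomalous diffusion) and for Brownian yet non-Gaussian
    (superstatistical) diffusion with Gamma or truncated-Gaussian diffusivity
    distributions; seeded Monte-Carlo trajectory generators for Brownian,
    fractional Brownian, superstatistical and subdiffusive continuous-time
    random-walk dynamics; a spin-phase engine that turns trajectory ensembles
    into synthetic attenuation curves with optional Rician noise; nonlinear
    least-squares model fitting with a classed result object; and the
    rescaling-based validation rules (g-squared collapse, pulse-duration
    difference constancy, b-value collapse, log-derivative trend) that decide
    which attenuation formula legitimately applies to a set of signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
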