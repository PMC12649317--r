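Package: qmstune
Title: Quadrupole Mass Spectrometer Auto-Tuning with Subpopulation-Ranked
    Differential Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a differential evolution optimizer whose population
    is ranked into elite, middle and inferior subpopulations with
    stage-dependent size ratios and adaptive mutation factors, alongside the
    classic DE strategies (rand/1, best/1, rand-to-best/1) and standard
    particle swarm optimization with a linearly decreasing inertia weight.
    Ships shifted-and-rotated Rastrigin and Lunacek bi-Rastrigin benchmark
    functions with a repeated-trial harness, a virtual quadrupole mass
    spectrometer (Gaussian peak shapes, linear mass-DAC and FWHM-OFFSET
    models, multiplicative detector noise, MCA accumulation), iterative
    linear calibration of the mass axis and mass resolution, and an
    instrument-in-the-loop automatic tuning pipeline with a univariate-search
    baseline, a key=value text-file exchange protocol and repeatability
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
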