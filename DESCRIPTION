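Package: dwrnr
Title: Interfacial Shear Rheology and Neutron Reflectometry Analysis for
    Double Wall-Ring / Langmuir Trough Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for simultaneous interfacial shear rheology
    and specular neutron reflectometry measurements on fluid interfaces.
    Inverts double wall-ring (DWR) torque/angular-displacement waveforms into
    interfacial dynamic shear moduli through a flow-field-based scheme that
    solves the single-component oscillatory Stokes problem with the
    Boussinesq-Scriven interfacial stress balance, and fits specular
    reflectivity curves with a molecularly constrained two-layer lipid
    monolayer model co-refined across isotopic contrasts.  A forward
    simulator of the instrument (second-order rotor dynamics, Gaussian
    channel noise, 16-bit quantization, counting noise on reflectivity)
    makes the full pipeline testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
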