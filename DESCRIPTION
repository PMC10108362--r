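Package: sabresim
Title: Spin-Dynamics Simulation of SABRE and LIGHT-SABRE Hyperpolarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density-matrix simulation of signal amplification by reversible
    exchange (SABRE) hyperpolarization of 1-13C-pyruvate at microtesla fields.
    Implements the generalized Liouville-von Neumann equation with a
    parahydrogen chemical-exchange superoperator, lab-frame and doubly
    rotating-frame Hamiltonians with continuous-wave (SLIC/LIGHT-SABRE)
    drives, analytic matching-condition theory (level anti-crossings, magic
    angle, SABRE-SHEATH field condition), protocol and readout emulation
    (direct transverse detection, crusher plus 90-degree pulses, SEPP),
    two-dimensional amplitude/offset polarization scans, ultralow-field
    spectrum synthesis with exchange narrowing, mono-exponential build-up
    fitting, and seeded generators for experiment-like synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
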