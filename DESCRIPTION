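Package: poroinject
Title: Multi-Network Poroelastic Simulation of Subcutaneous Drug Injection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of large-volume subcutaneous injection of
    monoclonal antibodies into a three-compartment (interstitium, blood
    capillaries, lymphatic capillaries) poroelastic mixture.  The model couples
    small-strain tissue mechanics, Darcy flow in each fluid network,
    pressure-driven transmural fluid exchange, and upwinded advection-diffusion
    drug transport on an axisymmetric structured grid, integrated in time with a
    second-order generalized-alpha scheme.  Includes a long-time transport-only
    absorption stage with depot-clearance decay fitting, Terzaghi and
    manufactured-solution verification benchmarks, and tools for probe series,
    plume diagnostics, and VTK/CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
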