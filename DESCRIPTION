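Package: ibstokes
Title: Immersed Boundary Simulation of Stokes Flow Driven by Elastic Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates two-dimensional Stokes flow driven by massless elastic
    immersed boundaries (closed strings and clamped filaments) on a periodic
    Cartesian grid. Lagrangian tension and bending forces are spread to the
    fluid grid through a compactly supported discrete delta kernel, the
    pressure and velocity fields are obtained from three periodic Poisson
    problems solved exactly by spectral diagonalization of the 5-point
    Laplacian, and structure positions are advanced with the interpolated
    local fluid velocity. Ships three ready-made scenarios: a relaxing star
    membrane, a bending clamped filament, and a filament whose induced flow
    deforms a passive circular membrane.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
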