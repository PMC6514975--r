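Package: racingarray
Title: Field Simulation and Multi-Focus Pattern Synthesis for Spherical-Cap Annular Ultrasound Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates contact-lens shaped ("racing") annular ultrasound arrays
    on a spherical cap for noninvasive retinal neurostimulation. Elements are
    tiled in concentric rings on the cap and discretized into weighted surface
    quadrature points; a discretized Rayleigh-Sommerfeld forward operator maps
    per-element complex excitations to acoustic pressures at arbitrary field
    points. Prescribed multi-focus pressure patterns are inverted by the
    truncated-SVD minimum-norm pseudoinverse and its iteratively weighted,
    amplitude-equalizing refinement. Includes focal-spot metrology (full width
    at half maximum of intensity profiles), grating-lobe pitch and aperture
    reports, depth-scan and bitmap-pattern experiments, regulatory intensity
    threshold reports, and YAML/JSON scenario configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
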