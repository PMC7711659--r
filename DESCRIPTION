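Package: nplemc
Title: Ion Transport in Nanopores and Channels by Coupled Nernst-Planck and
    Local Equilibrium Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-model simulation of steady-state ionic transport through
    biological ion channels and synthetic nanopores.  Electrolytes are treated
    in the Primitive Model (charged hard spheres in a uniform dielectric) and
    sampled with a Local Equilibrium Monte Carlo engine in which the
    electrochemical potential varies between subvolumes of the simulation
    cell.  The sampled concentration field is coupled self-consistently to the
    Nernst-Planck equation so that the converged flux satisfies the continuity
    equation.  Builders are provided for cylindrical nanopores with bipolar,
    unipolar and localized surface-charge patterns and for a reduced model of
    the ryanodine receptor calcium channel, together with analyzers for the
    device functions: current, chord and slope conductance, cation
    selectivity, and rectification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
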