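Package: electrotick
Title: Electrostatics of Passive Tick Attraction to Charged Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the electrostatic interaction between charged vertebrate
    hosts and questing ticks. Provides finite-volume Laplace solvers
    (axisymmetric and nested three-dimensional) for the electrode-over-plate
    laboratory rig and for grounded-vegetation/charged-host scenes, an
    image-charge analytic oracle for the sphere-plane geometry, a
    zero-intercept threshold-law model relating electrode distance to the
    voltage needed to lift a tick against gravity, mechanism-discrimination
    force models (induced polarization versus fixed surface charge), the
    associated statistical procedures (Pearson chi-square with adjusted
    residuals, Wald binomial intervals, bootstrap median intervals,
    permutation Mann-Whitney, Levene's test, forced-origin regression), and
    seed-reproducible generators for the staircase-threshold, fixed-voltage
    lift and polarity-comparison experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
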