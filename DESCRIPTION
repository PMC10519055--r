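Package: owosim
Title: Virtual Distal Femoral Osteotomy Simulation and TT-TG Metrology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a lateral opening-wedge distal femoral osteotomy on
    synthetic three-dimensional knee landmark models and measures the
    tibial tuberosity-trochlear groove (TT-TG) distance against the
    posterior condylar line in the fixed axial plane, across a schedule of
    varus correction angles. Provides a calibrated generator of synthetic
    valgus-knee cohorts, exact rigid rotations about anatomical axes, a
    closed-form pendulum-effect model with a least-squares estimator for
    its parameters, exact and normal-approximation Wilcoxon signed-rank
    tests, Pearson correlation and per-step slope summaries, a Fisher-z
    sample-size calculation for correlations, and an optional parametric
    triangle-mesh layer with STL input/output and posterior-landmark
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
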