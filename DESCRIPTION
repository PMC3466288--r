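Package: impedadapt
Title: Trial-by-Trial Learning of Force and Impedance in Arm Movements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a planar two-joint, six-muscle human arm that adapts
    to novel stable and unstable dynamics. The motor command combines a
    learned feedforward activation with a delayed, V-shaped feedback response
    to muscle stretch and shortening. Trial-by-trial gradient descent on a
    cost of movement error and effort updates the feedforward command over a
    Gaussian radial-basis-function representation of the joint state space
    (centers placed by K-means), so that learning generalizes across
    movements. Includes the classic force-field environments (velocity
    dependent curl fields, direction-variant fields, a divergent unstable
    field with a safety barrier), protocol drivers for movement
    generalization, field-granularity and multi-direction impedance-learning
    experiments, and metrics such as path axis ratios, velocity-profile
    correlations and endpoint stiffness ellipses.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
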