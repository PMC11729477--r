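Package: gaitcom
Title: Agreement Between Lumbar-IMU and Camera-Based Whole-Body
    Center-of-Mass Accelerations During Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing whole-body center-of-mass (CoM)
    acceleration derived from multi-segment motion-capture data against
    acceleration measured by a single inertial sensor worn at the fifth
    lumbar vertebra (L5). Implements the 13-link segmental weighted-sum
    CoM model with Dempster anthropometrics, zero-lag Butterworth signal
    conditioning, finite-difference differentiation, heel-strike
    detection from marker kinematics and from trunk accelerations via a
    Gaussian continuous-wavelet transform, gait-cycle segmentation and
    101-node time normalization, pooled Pearson and Bland-Altman
    agreement analysis, and one-dimensional statistical parametric
    mapping (repeated-measures ANOVA and paired-t fields) with
    random-field-theory thresholds validated against a permutation
    oracle. Ships a synthetic gait generator with analytically known CoM
    trajectories and heel-strike times so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
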