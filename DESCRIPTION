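Package: stridenet
Title: Kinematics-Only Detection of Foot-Strike and Toe-Off in Treadmill
    Running with a Bidirectional LSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Detects foot-strike and toe-off within treadmill running gait
    cycles from four kinematic channels (distal-tibia anteroposterior
    velocity, ankle dorsi/plantar-flexion angle, foot centre-of-mass
    anteroposterior and vertical velocity) using a bidirectional LSTM
    sequence classifier written from first principles. Includes the
    force-based ground-truth construction (50 N vertical ground reaction
    force threshold with a loading-rate quality-control filter), zero-lag
    Butterworth preprocessing, participant-wise cross-validation splits,
    non-parametric Bland-Altman agreement statistics, a joint-angle
    sensitivity analysis, and a synthetic treadmill-gait generator so the
    whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
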