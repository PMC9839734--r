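Package: equigrf
Title: Predicting Equine Vertical Ground Reaction Forces from Body-Mounted IMU Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting continuous vertical
    ground reaction force (GRFz) curves and discrete peak parameters of all four
    horse limbs from body-mounted inertial measurement unit (IMU) signals. Provides
    a physics-grounded synthetic gait generator for walk and trot treadmill
    locomotion, the IMU conditioning chain (dual-range acceleration merging,
    standstill calibration, cross-correlation stream synchronization, body-mass
    normalization), stride segmentation, dataset construction, a bilayer
    bidirectional LSTM sequence regressor trained with Adam (implemented in
    RcppArmadillo), and evaluation via stride RMSE, correlation, Robinson symmetry
    indices and Bland-Altman agreement, including the comparison of IMU node sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
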