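Package: bomilearn
Title: Forward and Inverse Internal-Model Learning Dynamics for
    Body-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of motor learning through a redundant
    body-machine interface. Implements the coupled first-order gradient
    dynamics by which a learner concurrently acquires a forward model of a
    many-to-one linear body-to-cursor map and a right-inverse model used to
    plan reaching movements; PCA-based interface calibration from motor
    babbling; a randomized-block center-out reaching protocol;
    moving-window least-squares identification of the inverse model;
    reaching, inverse-model, forward-model and prediction error metrics;
    exponential learning-curve fitting; and a synthetic-subject generator
    that emulates the statistical structure of calibration and training
    data. Trial logs and learning curves are tibbles, fitted objects have
    broom-style tidy() and glance() methods, and each result type has a
    ggplot2 autoplot() method.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
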