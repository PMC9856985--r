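Package: restwatch
Title: Rest-Activity Rhythm, Sleep and Survival Modelling for Wrist Actigraphy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for prognostic modelling in advanced-cancer cohorts from
    minute-epoch wrist actigraphy, consensus sleep diaries and routine clinical
    data. Computes rest-activity rhythm metrics (dichotomy index I<O with full
    and restricted windows, 24-hour autocorrelation r24, mean daily activity,
    mean wake activity), Actiware-style sleep/wake scoring and per-night sleep
    parameters, assembles an encoded and imputed feature table joined to a
    right-censored survival outcome, and fits regularised Cox models (ridge,
    elastic net, lasso) with cross-validated lambda selection, out-of-fold
    hazard prediction, Kaplan-Meier median-split evaluation and selection
    consistency. A synthetic cohort generator with known ground truth makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
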