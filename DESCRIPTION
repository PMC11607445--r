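Package: abxselect
Title: Counterfactual Antibiotic Selection for Sepsis with Neural Controlled Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online-updateable counterfactual disease-progression forecasting and
    side-effect-constrained antibiotic selection for sepsis patients. Implements a
    treatment-effect controlled differential equation model (neural CDE encoder with
    rectilinear control paths, neural ODE decoder, adversarial confounding balancing),
    Sepsis-3 / SOFA / stage-1 acute kidney injury rule engines, an iterative
    contraindication-aware antibiotic selector over Vancomycin, Ceftriaxone and
    Piperacillin/Tazobactam, evaluation procedures (forecast-error grids, side-effect
    contrasts, counterfactual matching, average treatment improvement), and a
    confounded synthetic electronic-health-record simulator with counterfactual
    ground truth for end-to-end testing without restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
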