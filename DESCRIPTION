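Package: afedyn
Title: Population-Dynamics Modeling of Anterior Foregut Endoderm Differentiation to Lung Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the in vitro differentiation of anterior foregut
    endoderm (AFE) into NKX2-1+ lung progenitors (LPs) as a family of candidate
    ordinary-differential-equation population models coupled to glucose and
    lactate dynamics. Provides heteroscedastic maximum-likelihood calibration
    with multistart differential-evolution plus Nelder-Mead optimization, BIC
    model selection on a held-out selection split, structural and
    profile-likelihood practical identifiability analyses, variance-based Sobol
    sensitivity analysis, model-based selection of sampling schedules by
    synthetic-data inference error, and in silico protocol predictions for
    split-ratio and media-change interventions. A synthetic-data generator
    reproduces the statistical design of the underlying four-condition
    experiment so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
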