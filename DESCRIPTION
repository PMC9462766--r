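Package: shootopt
Title: Neural-Network Surrogate Modelling and Multi-Objective
    Optimization of Plant Tissue Culture Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models in vitro shoot proliferation responses (shoot number,
    shoot length, callus weight) of factorial plant-growth-regulator
    experiments with single-hidden-layer perceptrons trained by
    Bayesian-regularized Levenberg-Marquardt, then searches the hormone
    concentration space with a real-coded elitist non-dominated sorting
    genetic algorithm (NSGA-II) to recommend a culture medium that jointly
    maximizes shoot number and length while minimizing callus formation.
    Includes ideal-point selection on the Pareto front, variable
    sensitivity (VSE/VSR) ranking of inputs, a synthetic dose-response
    generator with planted optima for validation, and a packaged 64-cell
    wallflower (Erysimum cheiri) factorial dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), nnet, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
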