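Package: lacoptim
Title: Cost-Benefit Optimality and Experimental Evolution of lac Operon
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of decoupled lac operon regulation in
    Escherichia coli, where a gratuitous inducer (IPTG) and a non-inducing
    carbon source (phenyl-beta-D-galactoside, Pgal) separate the regulatory
    and metabolic roles of the operon. Implements the cost-benefit growth
    model g(I,P) = g0 - eta(Z) + B(Z,P) with Hill induction and competitive
    anti-induction, derived optimality quantities (optimal expression and
    inducer levels, cost-benefit balance point, optimality-curve inflection),
    growth-landscape fitting and interpolation, cross-environment tradeoff
    (Pareto front) analysis, a serial-dilution evolution simulator with
    selection-coefficient fitting, and a calibrated synthetic-data generator
    for plate-reader growth and expression assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    MASS,
    mgcv,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
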