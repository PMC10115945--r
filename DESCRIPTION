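Package: glycopt
Title: Virtual-Patient Glucose-Insulin Simulation and Evolutionary
    Optimization of Meal and Insulin Schedules in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the daily plasma glucose and insulin dynamics of
    virtual patients with type 2 diabetes using a compartmental
    meal-simulation model (gastrointestinal glucose transit, endogenous
    glucose production, insulin-dependent and -independent utilization,
    renal excretion, glucose-controlled insulin secretion, and subcutaneous
    insulin delivery), and optimizes daily meal sizes, meal times, prandial
    insulin boluses and a constant basal pump infusion with an elitist
    evolutionary algorithm whose mutation operator conserves total daily
    carbohydrate intake. Includes glycemic scoring (daily extrema, 2-h
    postprandial glucose, time-in-range bands) against American Diabetes
    Association targets, three built-in virtual patients of increasing
    disease severity, and reproducible seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
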