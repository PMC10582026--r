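Package: oxitrain
Title: Indirect Calorimetry, Fat Oxidation and Energy-Equated Training Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing indirect-calorimetry data from weight-management
    exercise trials in adolescents with obesity: stoichiometric substrate-oxidation
    rates (fat, carbohydrate, protein) from breath-averaged gas exchange, basal
    metabolic rate from ventilated-canopy recordings via the Weir equation,
    graded treadmill test analysis (peak oxygen uptake, O2 pulse, maximal fat
    oxidation and the Fatmax intensity, fat/carbohydrate crossover), design of
    energy-equated continuous and combined interval training sessions (20 kJ per
    kg fat-free mass), five-minute-window energy partitioning of recorded
    sessions, and the trial's group-by-time repeated-measures statistics with
    bias-corrected effect sizes. A calibrated synthetic metabolic-cart generator
    makes every stage of the pipeline testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
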