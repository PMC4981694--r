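Package: dietmodelr
Title: Individualized Dietary Prescription Modeling by Constraint Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individualized food-group serving prescriptions for
    dietary intervention trials. Estimates resting energy expenditure from
    Mifflin-type anthropometric equations, scales it by a physical-activity
    factor to an estimated energy requirement, and then chooses daily servings
    per food group by constrained nonlinear minimization of the Euclidean
    distance between achieved and target macronutrient energy percentages,
    subject to per-group serving minima and an energy cap. Includes food
    composition table input/output with group-level homogeneity statistics
    (coefficient-of-variation screening), a brute-force grid oracle for
    verifying the solver, method-versus-reference percent-difference
    comparison reports, and a seeded synthetic fixture generator emulating a
    trial food database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
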