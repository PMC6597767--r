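Package: ft4dose
Title: Personalized Anti-Thyroid Drug Dosing from Free Thyroxine Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for personalized titration of anti-thyroid drugs
    (carbimazole/methimazole) in Graves' disease. Free thyroxine (FT4)
    dynamics under Hill-type dose inhibition are described by a Bernoulli
    ordinary differential equation with a closed-form solution; per-patient
    parameters (synthesis rate, decay rate, IC50) are estimated from a few
    thyroid-function-test visits by constrained nonlinear optimization.
    What-if solvers compute, given any two of treatment time, daily dose and
    FT4 level, the third, supporting dose-grid tables, target-dose tables
    and trajectory curves. Includes a virtual-patient simulator, a cohort
    evaluation protocol and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
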