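Package: wheelcap
Title: Wheelchair-Specific Exercise Capacity Testing on Roller Ergometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for standardized, individualized
    wheelchair-specific exercise-capacity testing on an instrumented dual
    roller ergometer. Converts raw per-side torque/velocity traces (100 Hz)
    into handrim forces and power output, extracts the outcomes of the
    isometric strength test, 10 s sprint test, 30 s Wingate anaerobic test
    (WAnT) and graded exercise test (GXT), scales each test's resistance
    from the previous test's result via published regression equations,
    evaluates protocol validity (velocity, duration, heart-rate and RPE
    criteria), reconstructs cohort-level Theil-Sen regressions, and ships a
    synthetic ergometer-trace generator so the whole pipeline can be
    exercised end-to-end without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
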