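Package: kneemetry
Title: Radiographic Knee Alignment Angles and Rater Agreement Statistics
Version: 0.1.0
Authors@R:
    person("kneemetry", "developers", email = "kneemetry@example.org",
           role = c("aut", "cre"))
Description: Landmark-coordinate geometry for full-leg anteroposterior
    radiograph measurements of the lower limb: the hip-knee-ankle deviation
    (HKA), mechanical lateral distal femoral angle (mLDFA), mechanical medial
    proximal tibial angle (mMPTA), trochlear groove angle (TGA), and the
    trochlear groove bisector angle (BA). Companion reliability machinery for
    fully crossed subjects-by-observers(-by-occasions) measurement designs:
    two-way random-effects variance components, absolute-agreement intraclass
    correlation with F-based confidence intervals, limits of agreement with
    the mean (LOAM) for multiple observers, extended Bland-Altman plot data,
    and the Bland-Altman repeatability coefficient. Includes calibrated
    synthetic cohort generators (angle-level and landmark-level) so the whole
    pipeline is testable without radiographs, plus CSV/JSON readers, writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
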