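Package: octagree
Title: Rater Agreement and Treatment-Adequacy Adjudication for OCT-Guided
    Macular Oedema Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing visit-level cohorts in which spectral-domain
    OCT scans of eyes with diabetic macular oedema (DME) or macular oedema
    secondary to retinal vein occlusion (RVO) were graded independently by
    treating physicians and by reading centres (RCs). Provides grading
    harmonization and the foveal disease-activity definition, physician-vs-RC
    agreement statistics (cross-tabulations, confirmation rates, Cohen's
    kappa, paired thickness comparisons), longitudinal fluid-change
    concordance and visual-acuity/thickness stability criteria, a rule-based
    per-visit adjudication of possible under- and overtreatment under a
    pro-re-nata anti-VEGF regimen, next-visit visual-acuity outcome
    distributions, a seeded synthetic cohort generator for testing every
    stage without patient data, and packaged count fixtures encoding the
    ORCA 24-month follow-up tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
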