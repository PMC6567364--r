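Package: emofun
Title: Statistical-Functional Features and Subject-Independent Emotion
    Classification for Multimodal Physiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multimodal physiological and behavioural
    recordings of participants watching emotion-elicitation film clips.
    Generates seeded synthetic cohorts with configurable emotion-conditional
    effects, segments and filters recordings by self-reported target-emotion
    ratings, extracts 727 statistical-functional features over four sensor
    modalities (facial action units, head pose, eye activity and gaze, skin
    conductance and peripheral temperature), selects features by one-way
    ANOVA, evaluates a one-vs-one RBF support vector machine under
    leave-one-subject-out cross-validation, and reproduces survey-side
    rating summaries with Welch t-tests and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
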