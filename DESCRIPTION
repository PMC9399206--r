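Package: lapgoals
Title: Automated GOALS Scoring of Laparoscopic Training from Instrument Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates Global Operative Assessment of Laparoscopic Skills
    (GOALS) ratings from motion-capture trajectories of laparoscopic
    instrument tips. Trajectories are smoothed and differentiated with a
    Savitzky-Golay filter, summarised into a catalogue of kinematic metrics
    (path length, velocity, acceleration, jerk, depth motion along the
    trocar axis, gripper activity, working volume, bimanual coordination),
    robust Z-score normalised, screened by Spearman correlation against
    rater-assigned GOALS items, and fed to four regression algorithms
    (support vector regression, PCA-SVR, ridge, partial least squares)
    tuned by grid search inside nested, repeated, stratified k-fold
    cross-validation. A skill-parameterised synthetic motion simulator with
    two noisy raters makes the whole pipeline testable without access to
    recorded sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    mixOmics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
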