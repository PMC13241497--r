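Package: actidiary
Title: Agreement Between Accelerometer ENMO and Diary-Derived MET Values
Version: 0.1.0
Authors@R:
    person("actidiary", "developers", email = "actidiary@example.org",
           role = c("aut", "cre"))
Description: Quantifies the agreement between physical-activity intensity
    measured by body-worn accelerometers (ENMO, the gravity-subtracted
    Euclidean norm of tri-axial acceleration) and energy expenditure derived
    from activity diaries via Compendium-style MET lookup, on 15-minute
    daytime epochs. Implements ENMO signal processing with a zero-phase
    Butterworth low-pass filter, diary-to-MET slot mapping with
    parallel-activity low/average/high levels, day- and participant-level
    inclusion rules, Min-Max normalization, Nelder-Mead fitting of a linear
    correction factor per sensor position and MET level, per-participant
    RMSE distributions with tremor-subgroup stratification, and a synthetic
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
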