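Package: rhythmconcord
Title: Concordance Evaluation of Ambulatory ECG Rhythm Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate beat-by-beat rhythm annotations of multi-day
    ambulatory electrocardiogram (Holter) recordings against a gold-standard
    consensus adjudication. Derives arrhythmia episodes from beat-level
    annotation tracks under a configurable clinical taxonomy (atrial
    fibrillation, supraventricular and ventricular tachycardia, asystole and
    pauses, atrioventricular block, ectopy, idioventricular rhythms), samples
    fixed-length adjudication strips with per-class quotas and
    source-population accounting, scores reader-versus-panel concordance with
    duration/beat-type overlap rules, and aggregates patient-level accuracy
    statistics: confusion-matrix metrics with bootstrap confidence intervals,
    false-negative and false-positive rates per 1,000 patients and per 1,000
    patient-days with prevalence weighting, and relative risk with Fisher's
    exact test. A synthetic cohort generator with configurable imperfect
    readers supports end-to-end validation without access to patient data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
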