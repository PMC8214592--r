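Package: dosewatch
Title: Rule-Based Surveillance of Paracetamol Dosing in Hospital
    Medication Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting paracetamol (acetaminophen) overdosing in
    electronic medication administration records (eMAR).  Provides a
    prospective polling alert engine with rolling 24-hour and 4-hour
    cumulative dose windows and weight-based (mg/kg) checks, a
    retrospective calendar-day gold-standard analysis with overdose cause
    attribution, a pharmacist triage layer that turns alert summaries into
    dose-reduction recommendations, detection-rate and alert-burden
    evaluation, and a seedable synthetic inpatient cohort generator with
    injected overdose mechanisms and ground-truth labels.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
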