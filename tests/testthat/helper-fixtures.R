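# Fixture builders shared across the suite.  Everything is constructed in
# code; no stored data.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# a minimal administration row with sensible defaults
adm_row <- function(record_id = "R1", patient_id = "P1", product_id = "tab500",
                    dose_amount = 2, dose_unit = "tablet", route = "oral",
                    admin_time = ts("2017-03-01 08:00"),
                    entry_time = admin_time + 120,
                    schedule_tag = "scheduled") {
  tibble::tibble(record_id = record_id, patient_id = patient_id,
                 product_id = product_id, dose_amount = dose_amount,
                 dose_unit = dose_unit, route = route,
                 admin_time = admin_time, entry_time = entry_time,
                 schedule_tag = schedule_tag)
}

# n standard 1 g doses for one patient at given times
adm_series <- function(times, patient_id = "P1", dose_mg = 1000, route = "oral",
                       entry_offset_min = 2) {
  times <- ts(times)
  tibble::tibble(
    record_id = sprintf("%s-R%03d", patient_id, seq_along(times)),
    patient_id = patient_id,
    product_id = "tab500",
    dose_amount = dose_mg / 500,
    dose_unit = "tablet",
    route = route,
    admin_time = times,
    entry_time = times + entry_offset_min * 60,
    schedule_tag = "scheduled",
    dose_mg = dose_mg
  )
}

stay_row <- function(patient_id = "P1", age_years = 60L,
                     admission = ts("2017-02-25 10:00"),
                     discharge = ts("2017-03-20 10:00"),
                     risk_flags = "", general_consent = TRUE) {
  tibble::tibble(patient_id = patient_id, age_years = age_years,
                 admission = admission, discharge = discharge,
                 risk_flags = risk_flags, general_consent = general_consent)
}

weight_row <- function(patient_id = "P1", measured_at = ts("2017-02-28 08:00"),
                       weight_kg = 70) {
  tibble::tibble(patient_id = patient_id, measured_at = measured_at,
                 weight_kg = weight_kg)
}

no_weights <- function() weight_row()[0, ]

# brute-force trailing-window oracle, independent of the engine internals
brute_window_mg <- function(history, t, hours = 24) {
  keep <- history$admin_time > t - hours * 3600 & history$admin_time <= t
  sum(history$dose_mg[keep], na.rm = TRUE)
}

# random small administration stream for property tests
random_stream <- function(n_dose, patient_id = "P1") {
  t0 <- ts("2017-06-01 00:00")
  times <- t0 + sort(sample(0:(5 * 24 * 60), n_dose)) * 60
  tibble::tibble(
    record_id = sprintf("%s-R%03d", patient_id, seq_len(n_dose)),
    patient_id = patient_id,
    product_id = "tab500",
    dose_amount = 1,
    dose_unit = "tablet",
    route = "oral",
    admin_time = times,
    entry_time = times + sample(0:30, n_dose, replace = TRUE) * 60,
    schedule_tag = "scheduled",
    dose_mg = sample(c(250, 500, 1000), n_dose, replace = TRUE)
  )
}
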