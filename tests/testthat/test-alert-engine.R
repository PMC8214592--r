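# Polling engine: window arithmetic, forward-dated-record policies,
# classification boundaries, display policy, summaries.

test_that("rolling 24-h dose matches a brute-force window sum under include", {
  set.seed(101)
  for (rep in 1:50) {
    h <- random_stream(sample(1:20, 1))
    t <- h$admin_time[sample(nrow(h), 1)] + sample(-60:600, 1) * 60
    expect_equal(rolling_dose_24h(h, t, policy = "include"),
                 brute_window_mg(h, t))
  }
})

test_that("the 24-h window is half-open: a dose exactly 24 h old is excluded", {
  h <- adm_series(c("2017-03-01 08:00", "2017-03-02 08:00"))
  expect_equal(rolling_dose_24h(h, ts("2017-03-02 08:00")), 1000)
  expect_equal(rolling_dose_24h(h, ts("2017-03-02 08:01")), 1000)
  # one minute inside the window, both doses count
  h2 <- adm_series(c("2017-03-01 08:01", "2017-03-02 08:00"))
  expect_equal(rolling_dose_24h(h2, ts("2017-03-02 08:00")), 2000)
  expect_equal(rolling_dose_24h(h[0, ], ts("2017-03-02 08:00")), 0)
})

test_that("forward-dated records are dropped under skip and kept under include", {
  past <- adm_series(c("2017-03-01 02:00", "2017-03-01 08:00",
                       "2017-03-01 14:00", "2017-03-01 20:00"))
  fwd <- adm_series("2017-03-01 23:30", entry_offset_min = -30) # entered 30 min early
  fwd$record_id <- "P1-fwd"
  h <- dplyr::bind_rows(past, fwd)
  t <- ts("2017-03-01 23:30")
  expect_equal(rolling_dose_24h(h, t, policy = "include"), 5000)
  expect_equal(rolling_dose_24h(h, t, policy = "skip_permanently"), 4000)
  # still excluded at a later evaluation time ("permanently")
  expect_equal(rolling_dose_24h(h, t + 3600, policy = "skip_permanently"), 4000)
  expect_equal(rolling_dose_24h(h, t, policy = "defer_until_due"), 5000)
})

test_that("interval since last dose handles first doses and exact boundaries", {
  h <- adm_series(c("2017-03-01 08:00", "2017-03-01 11:30"))
  expect_true(is.na(interval_since_last(h[0, ], ts("2017-03-01 08:00"))))
  expect_equal(interval_since_last(h[1, ], ts("2017-03-01 11:30")), 210)
  expect_equal(interval_since_last(h[1, ], ts("2017-03-01 12:00")), 240)
})

test_that("relative dose uses the latest prior weight and withholds stale ratios", {
  w <- weight_row(measured_at = ts("2017-02-27 08:00"), weight_kg = 50)
  r <- relative_dose(3100, ts("2017-03-01 08:00"), w)
  expect_equal(r$status, "ok")
  expect_equal(r$mg_per_kg, 62)
  expect_equal(relative_dose(3100, ts("2017-03-01 08:00"), no_weights())$status,
               "no_weight")
  old <- relative_dose(3100, ts("2017-03-19 08:00"), w) # 20 days later
  expect_equal(old$status, "old_weight")
  expect_true(is.na(old$mg_per_kg))
  expect_equal(old$weight_kg, 50) # weight still displayed alongside the alert
  # exactly 14 days is not yet stale; 15 days is
  expect_equal(relative_dose(1000, ts("2017-03-13 08:00"), w)$status, "ok")
  expect_equal(relative_dose(1000, ts("2017-03-14 08:00"), w)$status, "old_weight")
})

test_that("classification bands are strict with half-open edges", {
  ok <- list(status = "ok", mg_per_kg = 50)
  expect_equal(classify_administration(4000, 1000, ok), character(0))
  expect_equal(classify_administration(4001, 1000, ok), "A2")
  expect_equal(classify_administration(5000, 1000, ok), "A2")
  expect_equal(classify_administration(5001, 1000, ok), "A1")
  expect_equal(classify_administration(6000, 1000, ok), "A1")
  expect_equal(classify_administration(3000, 1000, list(status = "ok", mg_per_kg = 60)),
               character(0))
  expect_equal(classify_administration(3000, 1000, list(status = "ok", mg_per_kg = 60.1)),
               "A3")
  expect_equal(classify_administration(3000, 2000, ok), "A4")
  expect_equal(classify_administration(3000, 1000, list(status = "no_weight")), "A5")
  expect_equal(classify_administration(3000, 1000, list(status = "old_weight")), "A5a")
  expect_equal(classify_administration(NA, NA, ok, dose_ok = FALSE), "A0")
  expect_setequal(classify_administration(5500, 2000, list(status = "no_weight")),
                  c("A1", "A4", "A5"))
})

test_that("five 1 g doses at 4 h spacing produce a 4-5 g band alert at the fifth dose", {
  h <- adm_series(sprintf("2017-03-01 %02d:00", c(4, 8, 12, 16, 20)))
  alerts <- run_engine(h, weight_row(weight_kg = 80), stay_row(),
                       engine_config(forward_dated_policy = "include",
                                     display_policy = "show_all"))
  # window at the 5th dose is exactly 5000 mg: band alert, not over-5g
  a2 <- alerts[alerts$category == "A2", ]
  expect_equal(a2$trigger_record_id, "P1-R005")
  expect_equal(a2$window_dose_mg, 5000)
  expect_equal(sum(alerts$category == "A1"), 0)
  # doses 4 h apart never fire the short-interval alert
  expect_equal(sum(alerts$category == "A4"), 0)
})

test_that("a single therapeutic dose with a recent weight raises no alerts", {
  h <- adm_series("2017-03-01 08:00")
  alerts <- run_engine(h, weight_row(measured_at = ts("2017-02-28 08:00"),
                                     weight_kg = 70),
                       stay_row(), engine_config())
  expect_equal(nrow(alerts), 0)
  empty <- run_engine(h[0, ], no_weights(), stay_row(), engine_config())
  expect_equal(nrow(empty), 0)
})

test_that("the engine under skip_permanently reproduces the forward-dating blind spot", {
  past <- adm_series(sprintf("2017-03-01 %02d:00", c(3, 9, 15, 21)))
  fwd <- adm_series("2017-03-02 01:00", entry_offset_min = -30)
  fwd$record_id <- "P1-fwd"
  h <- dplyr::bind_rows(past, fwd)
  w <- weight_row(weight_kg = 80)
  inc <- run_engine(h, w, stay_row(),
                    engine_config(forward_dated_policy = "include",
                                  display_policy = "show_all"))
  skp <- run_engine(h, w, stay_row(),
                    engine_config(forward_dated_policy = "skip_permanently",
                                  display_policy = "show_all"))
  expect_true("A2" %in% inc$category)  # 5000 mg seen by the corrected engine
  expect_false("A2" %in% skp$category) # legacy engine never sums past 4000
  expect_false("A1" %in% skp$category)
  # alerted patients under skip are a subset of those under include
  expect_true(all(unique(skp$patient_id) %in% unique(inc$patient_id)))
})

test_that("poll interval does not change evaluations when nothing is forward-dated", {
  set.seed(77)
  streams <- lapply(1:5, function(i) {
    s <- random_stream(12, patient_id = paste0("P", i))
    s$entry_time <- s$admin_time + sample(0:20, 12, replace = TRUE) * 60
    s
  })
  h <- dplyr::bind_rows(streams)
  w <- weight_row(patient_id = "P1", weight_kg = 55)
  stays <- stay_row()
  key <- function(a) {
    a <- a[order(a$trigger_record_id, a$category), ]
    a[, c("trigger_record_id", "category", "window_dose_mg", "mg_per_kg")]
  }
  a1 <- run_engine(h, w, stays, engine_config(poll_interval_min = 1,
                                              forward_dated_policy = "include"))
  a5 <- run_engine(h, w, stays, engine_config(poll_interval_min = 5,
                                              forward_dated_policy = "include"))
  expect_equal(key(a1), key(a5))
})

test_that("engine runs are deterministic", {
  tabs <- generate_cohort(sim_config(n_patients = 15, seed = 4))
  cl <- clean_emar(tabs)
  a <- run_engine(cl$administrations, tabs$weights, tabs$stays, engine_config())
  b <- run_engine(cl$administrations, tabs$weights, tabs$stays, engine_config())
  expect_identical(a, b)
})

test_that("legacy display policy suppresses same-tick band and mg/kg alerts, not A1", {
  alerts <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P2", "P1"),
    category = c("A4", "A2", "A3", "A2", "A1"),
    fired_at = ts("2017-03-01 08:05"),
    trigger_record_id = c("r1", "r1", "r1", "r9", "r1"),
    window_dose_mg = NA_real_, mg_per_kg = NA_real_,
    interval_minutes = NA_real_, weight_used_kg = NA_real_,
    weight_age_days = NA_real_
  )
  shown <- apply_display_policy(alerts, "legacy_overshadow")
  expect_setequal(shown$category[shown$patient_id == "P1"], c("A4", "A1"))
  expect_equal(shown$category[shown$patient_id == "P2"], "A2") # no A4 there
  expect_equal(nrow(apply_display_policy(alerts, "show_all")), nrow(alerts))
})

test_that("alert summaries conserve counts across patients", {
  tabs <- generate_cohort(sim_config(n_patients = 20, seed = 6))
  cl <- clean_emar(tabs)
  a <- run_engine(cl$administrations, tabs$weights, tabs$stays,
                  engine_config(forward_dated_policy = "include"))
  s <- summarize_alerts(a)
  expect_equal(sum(s$n_alerts), nrow(a))
  expect_true(all(s$first_fired_at <= s$last_fired_at))
  expect_equal(nrow(summarize_alerts(a[0, ])), 0)
})
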