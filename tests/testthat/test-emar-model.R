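# Domain model: file I/O, validation, cleaning rules, dose normalization.

test_that("tables round-trip through write/read unchanged", {
  dir <- withr::local_tempdir()
  tabs <- generate_cohort(sim_config(n_patients = 8, seed = 3))
  write_emar_tables(tabs, dir)
  back <- read_emar_tables(dir)
  for (tab in c("administrations", "weights", "stays", "orders", "catalog")) {
    a <- as.data.frame(tabs[[tab]])[, names(back[[tab]])]
    b <- as.data.frame(back[[tab]])
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, info = tab, ignore_attr = "rejected")
  }
})

test_that("an empty administrations file yields an empty record list", {
  dir <- withr::local_tempdir()
  tabs <- generate_cohort(sim_config(n_patients = 0, seed = 1))
  write_emar_tables(tabs, dir)
  back <- read_emar_tables(dir)
  expect_equal(nrow(back$administrations), 0)
})

test_that("schema violations are reported by column and record", {
  dir <- withr::local_tempdir()
  tabs <- generate_cohort(sim_config(n_patients = 2, seed = 5))
  write_emar_tables(tabs, dir)
  f <- file.path(dir, "administrations.csv")
  df <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(df[, setdiff(names(df), "dose_unit")], f)
  expect_error(read_emar_tables(dir), "dose_unit")
  readr::write_csv(dplyr::mutate(df, admin_time = dplyr::if_else(
    record_id == df$record_id[1], "not-a-time", as.character(admin_time))), f)
  expect_error(read_emar_tables(dir), df$record_id[1])
})

test_that("records entered more than 60 min before administration are rejected", {
  ok <- adm_row(record_id = "ok", entry_time = ts("2017-03-01 08:00") - 60 * 60)
  bad <- adm_row(record_id = "bad", entry_time = ts("2017-03-01 08:00") - 90 * 60)
  out <- validate_administrations(dplyr::bind_rows(ok, bad))
  expect_equal(out$record_id, "ok")
  rej <- attr(out, "rejected")
  expect_equal(rej$record_id, "bad")
  expect_equal(rej$reject_reason, "forward_entry_violation")
})

test_that("cohort filter keeps adults with consent, inclusively at 18", {
  adm <- dplyr::bind_rows(
    adm_row(record_id = "a", patient_id = "P17"),
    adm_row(record_id = "b", patient_id = "P18"),
    adm_row(record_id = "c", patient_id = "Pnc"),
    adm_row(record_id = "d", patient_id = "Punknown")
  )
  stays <- dplyr::bind_rows(
    stay_row("P17", age_years = 17L),
    stay_row("P18", age_years = 18L),
    stay_row("Pnc", age_years = 50L, general_consent = FALSE)
  )
  out <- filter_cohort(adm, stays)
  expect_equal(out$record_id, "b")
  excl <- attr(out, "excluded")
  expect_equal(excl$minor, 1L)
  expect_equal(excl$no_consent, 1L)
  expect_equal(excl$orphan, 1L)
  # patient set of the output is a subset of the input
  expect_true(all(out$patient_id %in% adm$patient_id))
})

test_that("administrations outside the documented stay are excluded", {
  adm <- adm_row(admin_time = ts("2017-01-01 08:00"),
                 entry_time = ts("2017-01-01 08:05"))
  out <- filter_cohort(adm, stay_row()) # stay starts 2017-02-25
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "excluded")$outside_stay, 1L)
})

test_that("deduplication removes exact key duplicates only, idempotently", {
  a <- adm_row(record_id = "r1")
  dup <- adm_row(record_id = "r2", entry_time = a$admin_time + 600)
  other_dose <- adm_row(record_id = "r3", dose_amount = 1)
  once <- deduplicate_administrations(dplyr::bind_rows(a, dup, other_dose))
  expect_setequal(once$record_id, c("r1", "r3"))
  expect_equal(attr(once, "n_removed"), 1L)
  twice <- deduplicate_administrations(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = "n_removed")
  expect_equal(nrow(deduplicate_administrations(a[0, ])), 0)
})

test_that("implausible doses are repaired from the order, or excluded", {
  catalog <- paracetamol_catalog()
  orders <- tibble::tibble(
    order_id = "O1", patient_id = "P1", product_id = "tab500",
    dose_mg_per_admin = 1000, schedule = "08:00;20:00", route = "oral",
    valid_from = ts("2017-02-01 00:00"), valid_to = ts("2017-04-01 00:00")
  )
  one_mg <- adm_row(record_id = "tiny", dose_amount = 1, dose_unit = "mg")
  kilotab <- adm_row(record_id = "huge", dose_amount = 1000, dose_unit = "tablet")
  fine <- adm_row(record_id = "fine", dose_amount = 1000, dose_unit = "mg")
  no_order <- adm_row(record_id = "orphan", patient_id = "P9",
                      dose_amount = 1000, dose_unit = "g")
  out <- repair_implausible(dplyr::bind_rows(one_mg, kilotab, fine, no_order),
                            orders, catalog)
  expect_setequal(out$record_id, c("tiny", "huge", "fine"))
  expect_equal(out$dose_mg[out$record_id == "tiny"], 1000)
  expect_equal(out$dose_mg[out$record_id == "huge"], 1000)
  expect_equal(out$dose_mg[out$record_id == "fine"], 1000)
  expect_equal(attr(out, "n_unrepairable"), 1L)
  rep_log <- attr(out, "repairs")
  expect_setequal(rep_log$record_id, c("tiny", "huge"))
  expect_equal(rep_log$before_mg[rep_log$record_id == "huge"], 500000)
})

test_that("repair never touches a record already in the plausibility band", {
  catalog <- paracetamol_catalog()
  orders <- tibble::tibble(order_id = character(), patient_id = character(),
                           product_id = character(), dose_mg_per_admin = numeric(),
                           schedule = character(), route = character(),
                           valid_from = ts(character()), valid_to = ts(character()))
  set.seed(42)
  amounts <- sample(c(1, 2, 3, 4), 20, replace = TRUE) # 500-2000 mg as tablets
  adm <- dplyr::bind_rows(lapply(seq_along(amounts), function(i) {
    adm_row(record_id = paste0("r", i), dose_amount = amounts[i])
  }))
  out <- repair_implausible(adm, orders, catalog)
  expect_equal(out$dose_amount, adm$dose_amount)
  expect_equal(nrow(attr(out, "repairs")), 0)
})

test_that("paracetamol content normalizes across units and products", {
  catalog <- paracetamol_catalog()
  expect_equal(paracetamol_mg(list(dose_amount = 1, dose_unit = "g",
                                   product_id = "tab500"), catalog), 1000)
  expect_equal(paracetamol_mg(list(dose_amount = 2, dose_unit = "tablet",
                                   product_id = "tab500"), catalog), 1000)
  expect_equal(paracetamol_mg(list(dose_amount = 750, dose_unit = "mg",
                                   product_id = "tab500"), catalog), 750)
  # 10 mg/ml infusion: volume times concentration
  expect_equal(paracetamol_mg(list(dose_amount = 10, dose_unit = "ml",
                                   product_id = "ivsol10"), catalog), 100)
  expect_equal(paracetamol_mg(list(dose_amount = 100, dose_unit = "ml",
                                   product_id = "ivsol10"), catalog), 1000)
  expect_error(paracetamol_mg(list(dose_amount = 1, dose_unit = "tablet",
                                   product_id = "nope"), catalog), "nope")
})

test_that("the cleaning cascade reports counts per rule", {
  tabs <- generate_cohort(sim_config(n_patients = 10, seed = 9))
  cl <- clean_emar(tabs)
  expect_true(all(c("n_input", "n_duplicates_removed", "n_repaired",
                    "n_unrepairable_excluded", "n_output") %in% names(cl$report)))
  expect_lte(cl$report$n_output, cl$report$n_input)
  expect_true(all(!is.na(cl$administrations$dose_mg)))
  path <- withr::local_tempfile(fileext = ".json")
  write_cleaning_report(cl$report, path)
  expect_equal(jsonlite::read_json(path)$n_output, cl$report$n_output)
})
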