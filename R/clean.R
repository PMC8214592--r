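# Record cleaning: cohort filter, deduplication, implausible-value repair,
# and paracetamol content normalization.

#' Paracetamol content of one administration, in mg
#'
#' Normalizes a recorded dose to milligrams of paracetamol: `mg` passes
#' through, `g` is scaled by 1000, `tablet` and `ml` are multiplied by the
#' product's catalog content per unit (which also resolves combination
#' preparations to their paracetamol fraction).
#'
#' @param record A one-row administration tibble (or list) with
#'   `dose_amount`, `dose_unit`, `product_id`.
#' @param catalog Product catalog tibble.
#' @return Dose in mg (scalar).
#' @examples
#' cat <- paracetamol_catalog()
#' paracetamol_mg(list(dose_amount = 1, dose_unit = "g", product_id = "tab500"), cat)
#' paracetamol_mg(list(dose_amount = 2, dose_unit = "tablet", product_id = "tab500"), cat)
#' @export
paracetamol_mg <- function(record, catalog) {
  if (!record$product_id %in% catalog$product_id) {
    stop("unknown product: ", record$product_id, call. = FALSE)
  }
  mg <- dw_normalize_mg(record$dose_amount, record$dose_unit,
                        record$product_id, catalog)
  if (is.na(mg)) {
    stop("dose not normalizable for product ", record$product_id,
         " (unit '", record$dose_unit, "')", call. = FALSE)
  }
  mg
}

# vectorized normalization; NA (not an error) marks a non-normalizable dose
dw_normalize_mg <- function(dose_amount, dose_unit, product_id, catalog) {
  content <- catalog$paracetamol_mg_per_unit[match(product_id, catalog$product_id)]
  mg <- rep(NA_real_, length(dose_amount))
  mg[dose_unit == "mg"] <- dose_amount[dose_unit == "mg"]
  mg[dose_unit == "g"] <- dose_amount[dose_unit == "g"] * 1000
  per_unit <- dose_unit %in% c("tablet", "ml")
  mg[per_unit] <- dose_amount[per_unit] * content[per_unit]
  mg[is.na(dose_amount)] <- NA_real_
  mg
}

#' Add a normalized `dose_mg` column to an administration tibble
#'
#' Unknown products or unresolvable units yield `NA`, which the alert
#' engine surfaces as "dose not calculable" (A0) alerts rather than errors.
#'
#' @param administrations Administration tibble.
#' @param catalog Product catalog tibble.
#' @return The input with a `dose_mg` column appended.
#' @export
normalize_doses <- function(administrations, catalog) {
  dw_abort_missing_cols(administrations, c("dose_amount", "dose_unit", "product_id"),
                        "administrations")
  dplyr::mutate(
    administrations,
    dose_mg = dw_normalize_mg(.data$dose_amount, .data$dose_unit,
                              .data$product_id, catalog)
  )
}

#' Restrict administrations to the adult, consenting cohort
#'
#' Keeps records of patients aged `adult_age_min` or older (inclusive)
#' whose general consent is true, and whose administration time falls
#' within the documented stay.  Records for unknown patients are excluded
#' as orphans.
#'
#' @param administrations Administration tibble.
#' @param stays Stay tibble.
#' @param thresholds A [dose_thresholds()] object.
#' @return Filtered tibble; `attr(., "excluded")` counts removals per
#'   reason (`minor`, `no_consent`, `orphan`, `outside_stay`).
#' @export
filter_cohort <- function(administrations, stays, thresholds = dose_thresholds()) {
  a <- dplyr::left_join(
    administrations,
    dplyr::select(stays, "patient_id", "age_years", "admission", "discharge",
                  "general_consent"),
    by = "patient_id"
  )
  reason <- rep(NA_character_, nrow(a))
  reason[is.na(a$age_years)] <- "orphan"
  reason[is.na(reason) & a$age_years < thresholds$adult_age_min] <- "minor"
  reason[is.na(reason) & !a$general_consent] <- "no_consent"
  outside <- a$admin_time < a$admission | a$admin_time > a$discharge
  reason[is.na(reason) & outside] <- "outside_stay"
  kept <- administrations[is.na(reason), , drop = FALSE]
  attr(kept, "excluded") <- as.list(table(reason))
  kept
}

#' Drop duplicate administration records
#'
#' Two records are duplicates when they agree on
#' (`patient_id`, `product_id`, `admin_time`, `dose_amount`, `dose_unit`) -
#' the minimal key that removes double data entry without dropping
#' legitimate repeat doses.  The earliest-entered record of each key is
#' retained.  The operation is idempotent.
#'
#' @param administrations Administration tibble.
#' @return Deduplicated tibble; `attr(., "n_removed")` gives the count.
#' @export
deduplicate_administrations <- function(administrations) {
  key <- c("patient_id", "product_id", "admin_time", "dose_amount", "dose_unit")
  dw_abort_missing_cols(administrations, key, "administrations")
  out <- administrations |>
    dplyr::arrange(.data$entry_time, .data$record_id) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(key)), .keep_all = TRUE) |>
    dplyr::arrange(.data$patient_id, .data$admin_time, .data$record_id)
  attr(out, "n_removed") <- nrow(administrations) - nrow(out)
  out
}

#' Repair implausible recorded doses against the prescription order
#'
#' A record whose normalized paracetamol content falls outside the
#' plausibility band (default 100-2000 mg per administration; think
#' '1 mg', '1000 g' or '1000 tablets') is replaced by the dose of the
#' matching order (same patient and product, administration time within
#' the order's validity).  Records with no matching order are excluded as
#' unrepairable rather than guessed.  Records already inside the band are
#' never changed.
#'
#' @param administrations Administration tibble.
#' @param orders Prescription order tibble.
#' @param catalog Product catalog tibble.
#' @param thresholds A [dose_thresholds()] object (plausibility band).
#' @return Tibble with a `dose_mg` column; attributes `repairs` (tibble of
#'   record_id, before/after mg) and `n_unrepairable`.
#' @export
repair_implausible <- function(administrations, orders, catalog,
                               thresholds = dose_thresholds()) {
  a <- normalize_doses(administrations, catalog)
  implaus <- !is.na(a$dose_mg) &
    (a$dose_mg < thresholds$plaus_min_mg | a$dose_mg > thresholds$plaus_max_mg)
  repairs <- tibble::tibble(record_id = character(), before_mg = numeric(),
                            after_mg = numeric())
  drop <- logical(nrow(a))
  for (i in which(implaus)) {
    cand <- orders[orders$patient_id == a$patient_id[i] &
                     orders$product_id == a$product_id[i] &
                     orders$valid_from <= a$admin_time[i] &
                     orders$valid_to >= a$admin_time[i], , drop = FALSE]
    if (nrow(cand) == 0) {
      drop[i] <- TRUE
      next
    }
    cand <- cand[order(cand$valid_from, decreasing = TRUE), , drop = FALSE]
    repairs <- dplyr::bind_rows(repairs, tibble::tibble(
      record_id = a$record_id[i], before_mg = a$dose_mg[i],
      after_mg = cand$dose_mg_per_admin[1]
    ))
    a$dose_mg[i] <- cand$dose_mg_per_admin[1]
    a$dose_amount[i] <- cand$dose_mg_per_admin[1]
    a$dose_unit[i] <- "mg"
  }
  out <- a[!drop, , drop = FALSE]
  attr(out, "repairs") <- repairs
  attr(out, "n_unrepairable") <- sum(drop)
  out
}

#' Run the full cleaning cascade
#'
#' Cohort filter, deduplication, implausible-value repair and dose
#' normalization in sequence, with a per-rule cleaning report.
#'
#' @param tables Named list of the five tables (see [read_emar_tables()]).
#' @param thresholds A [dose_thresholds()] object.
#' @return List with `administrations` (cleaned, with `dose_mg`) and
#'   `report` (named list of counts removed/changed per rule).
#' @examples
#' cfg <- sim_config(n_patients = 5, seed = 1)
#' tabs <- generate_cohort(cfg)
#' cleaned <- clean_emar(tabs)
#' cleaned$report
#' @export
clean_emar <- function(tables, thresholds = dose_thresholds()) {
  a0 <- tables$administrations
  a1 <- filter_cohort(a0, tables$stays, thresholds)
  a2 <- deduplicate_administrations(a1)
  a3 <- repair_implausible(a2, tables$orders, tables$catalog, thresholds)
  report <- c(
    list(
      n_input = nrow(a0),
      n_rejected_at_read = nrow(attr(a0, "rejected") %||% data.frame())
    ),
    lapply(attr(a1, "excluded") %||% list(), as.integer),
    list(
      n_duplicates_removed = attr(a2, "n_removed"),
      n_repaired = nrow(attr(a3, "repairs")),
      n_unrepairable_excluded = attr(a3, "n_unrepairable"),
      n_output = nrow(a3)
    )
  )
  list(administrations = a3, report = report)
}

#' Write a cleaning report as JSON
#'
#' @param report The `report` element returned by [clean_emar()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
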