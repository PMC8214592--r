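# Tabular I/O for the five eMAR extract tables.
#
# All files are UTF-8 CSVs with a header row and ISO-8601 timestamps:
#   administrations.csv: record_id,patient_id,product_id,dose_amount,
#                        dose_unit,route,admin_time,entry_time,schedule_tag
#   weights.csv:         patient_id,measured_at,weight_kg
#   stays.csv:           patient_id,age_years,admission,discharge,
#                        risk_flags,general_consent
#   orders.csv:          order_id,patient_id,product_id,dose_mg_per_admin,
#                        schedule,route,valid_from,valid_to
#   catalog.csv:         product_id,paracetamol_mg_per_unit,unit_kind,
#                        is_combination
# risk_flags is a semicolon-joined token set; an order schedule is a
# semicolon-joined list of HH:MM clock times or the token "on_demand".

dw_schemas <- list(
  administrations = c("record_id", "patient_id", "product_id", "dose_amount",
                      "dose_unit", "route", "admin_time", "entry_time",
                      "schedule_tag"),
  weights = c("patient_id", "measured_at", "weight_kg"),
  stays = c("patient_id", "age_years", "admission", "discharge",
            "risk_flags", "general_consent"),
  orders = c("order_id", "patient_id", "product_id", "dose_mg_per_admin",
             "schedule", "route", "valid_from", "valid_to"),
  catalog = c("product_id", "paracetamol_mg_per_unit", "unit_kind",
              "is_combination")
)

dw_dose_units <- c("mg", "g", "tablet", "ml")
dw_routes <- c("oral", "iv", "rectal")
dw_schedule_tags <- c("scheduled", "on_demand", "unscheduled")
dw_risk_flags <- c("chronic_alcohol", "enzyme_inducer", "egfr_below_15",
                   "severe_hepatic_impairment")

dw_parse_time <- function(x, table, ids, col) {
  if (inherits(x, "POSIXct")) return(floor_minute(dw_time(x)))
  # failures surface as a row-level error below, not as readr warnings
  parsed <- suppressWarnings(readr::parse_datetime(as.character(x)))
  bad <- is.na(parsed) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("%s: unparseable %s for record(s) %s", table, col,
                 paste(head(ids[bad], 5), collapse = ", ")), call. = FALSE)
  }
  floor_minute(dw_time(parsed))
}

#' Read the five eMAR extract tables
#'
#' Reads and validates the administration, weight, stay, order and product
#' catalog CSVs.  Timestamps are normalized to minute resolution.
#' Administration rows violating structural invariants (non-positive dose,
#' unknown unit/route, or entry more than `forward_entry_max_min` minutes
#' before the administration time) are rejected and returned in the
#' `rejected` attribute of the administrations tibble rather than silently
#' kept.
#'
#' @param paths Named list or vector with elements `administrations`,
#'   `weights`, `stays`, `orders`, `catalog` giving file paths; or a single
#'   directory containing files with those names plus `.csv`.
#' @param thresholds A [dose_thresholds()] object (supplies the
#'   forward-entry allowance).
#' @return A named list of tibbles (`administrations`, `weights`, `stays`,
#'   `orders`, `catalog`).  `attr(x$administrations, "rejected")` holds the
#'   rejected rows with a `reject_reason` column.
#' @seealso [write_emar_tables()] for the inverse.
#' @export
read_emar_tables <- function(paths, thresholds = dose_thresholds()) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- as.list(file.path(paths, paste0(names(dw_schemas), ".csv")))
    names(paths) <- names(dw_schemas)
  }
  paths <- as.list(paths)
  missing <- setdiff(names(dw_schemas), names(paths))
  if (length(missing) > 0) {
    stop("missing table path(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(names(dw_schemas), function(tab) {
    f <- paths[[tab]]
    if (!file.exists(f)) stop(tab, ": file not found: ", f, call. = FALSE)
    df <- readr::read_csv(f, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    dw_abort_missing_cols(df, dw_schemas[[tab]], paste0(tab, ".csv"))
    df
  })
  names(raw) <- names(dw_schemas)

  adm <- raw$administrations
  adm <- tibble::tibble(
    record_id = adm$record_id,
    patient_id = adm$patient_id,
    product_id = adm$product_id,
    dose_amount = readr::parse_double(adm$dose_amount),
    dose_unit = adm$dose_unit,
    route = adm$route,
    admin_time = dw_parse_time(adm$admin_time, "administrations.csv", adm$record_id, "admin_time"),
    entry_time = dw_parse_time(adm$entry_time, "administrations.csv", adm$record_id, "entry_time"),
    schedule_tag = adm$schedule_tag
  )
  adm <- validate_administrations(adm, thresholds)

  wt <- raw$weights
  wt <- tibble::tibble(
    patient_id = wt$patient_id,
    measured_at = dw_parse_time(wt$measured_at, "weights.csv", wt$patient_id, "measured_at"),
    weight_kg = readr::parse_double(wt$weight_kg)
  )
  wt <- dplyr::filter(wt, !is.na(.data$weight_kg),
                      .data$weight_kg >= 20, .data$weight_kg <= 300)

  st <- raw$stays
  st <- tibble::tibble(
    patient_id = st$patient_id,
    age_years = readr::parse_integer(st$age_years),
    admission = dw_parse_time(st$admission, "stays.csv", st$patient_id, "admission"),
    discharge = dw_parse_time(st$discharge, "stays.csv", st$patient_id, "discharge"),
    risk_flags = ifelse(is.na(st$risk_flags), "", st$risk_flags),
    general_consent = readr::parse_logical(st$general_consent)
  )

  ord <- raw$orders
  ord <- tibble::tibble(
    order_id = ord$order_id,
    patient_id = ord$patient_id,
    product_id = ord$product_id,
    dose_mg_per_admin = readr::parse_double(ord$dose_mg_per_admin),
    schedule = ord$schedule,
    route = ord$route,
    valid_from = dw_parse_time(ord$valid_from, "orders.csv", ord$order_id, "valid_from"),
    valid_to = dw_parse_time(ord$valid_to, "orders.csv", ord$order_id, "valid_to")
  )

  cat <- raw$catalog
  cat <- tibble::tibble(
    product_id = cat$product_id,
    paracetamol_mg_per_unit = readr::parse_double(cat$paracetamol_mg_per_unit),
    unit_kind = cat$unit_kind,
    is_combination = readr::parse_logical(cat$is_combination)
  )

  list(administrations = adm, weights = wt, stays = st, orders = ord, catalog = cat)
}

#' Validate administration rows against structural invariants
#'
#' Rejects rows with non-positive dose, unknown dose unit or route, or an
#' entry time more than the forward-entry allowance (default 60 min) before
#' the administration time (the eMAR dialect permits documenting up to one
#' hour in advance, no more).
#'
#' @param administrations Administration tibble.
#' @param thresholds A [dose_thresholds()] object.
#' @return The retained rows; rejected rows (with `reject_reason`) are
#'   stored in the `rejected` attribute.
#' @export
validate_administrations <- function(administrations, thresholds = dose_thresholds()) {
  dw_abort_missing_cols(administrations,
                        c("record_id", "dose_amount", "dose_unit", "route",
                          "admin_time", "entry_time"),
                        "administrations")
  a <- administrations
  reason <- rep(NA_character_, nrow(a))
  reason[!is.na(a$dose_amount) & a$dose_amount <= 0] <- "nonpositive_dose"
  reason[is.na(a$dose_amount)] <- "missing_dose"
  reason[is.na(reason) & !(a$dose_unit %in% dw_dose_units)] <- "unknown_unit"
  reason[is.na(reason) & !(a$route %in% dw_routes)] <- "unknown_route"
  fwd <- as.numeric(a$admin_time) - as.numeric(a$entry_time) >
    thresholds$forward_entry_max_min * 60
  reason[is.na(reason) & fwd] <- "forward_entry_violation"
  kept <- a[is.na(reason), , drop = FALSE]
  rejected <- a[!is.na(reason), , drop = FALSE]
  rejected$reject_reason <- reason[!is.na(reason)]
  attr(kept, "rejected") <- rejected
  kept
}

#' Write the five eMAR tables as CSV
#'
#' Inverse of [read_emar_tables()]: writes `administrations.csv`,
#' `weights.csv`, `stays.csv`, `orders.csv` and `catalog.csv` into `dir`.
#' Clean tables round-trip field for field.
#'
#' @param tables Named list of tibbles as returned by [read_emar_tables()]
#'   or [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_emar_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
  for (tab in names(dw_schemas)) {
    df <- tables[[tab]]
    if (is.null(df)) stop("tables is missing element '", tab, "'", call. = FALSE)
    df <- dplyr::select(as.data.frame(df), dplyr::all_of(dw_schemas[[tab]]))
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- fmt_time(df[[col]])
    }
    readr::write_csv(df, file.path(dir, paste0(tab, ".csv")), progress = FALSE)
  }
  invisible(dir)
}
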