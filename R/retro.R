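# Retrospective gold standard: calendar-day dose totals, absolute and
# relative overdose classification, consecutive-day runs, and cause
# attribution.  Days split at local midnight, deliberately different from
# the engine's trailing 24-h windows (midnight-straddling schedules are a
# known source of artificial trailing-window overdoses).

#' Calendar-day paracetamol totals
#'
#' @param administrations Cleaned administration tibble with `dose_mg`.
#' @return Tibble with one row per (patient, date) holding `total_mg`,
#'   `n_administrations`, `routes_used` (sorted, comma-joined), and the
#'   day's first/last administration times (used for nearest-in-time
#'   weight lookup).  The grand total in mg is conserved.
#' @export
calendar_day_totals <- function(administrations) {
  if (nrow(administrations) == 0) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          total_mg = numeric(), n_administrations = integer(),
                          routes_used = character(),
                          first_admin = dw_num_time(numeric(0)),
                          last_admin = dw_num_time(numeric(0))))
  }
  administrations |>
    dplyr::filter(!is.na(.data$dose_mg)) |>
    dplyr::mutate(date = dw_date(.data$admin_time)) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::summarise(
      total_mg = sum(.data$dose_mg),
      n_administrations = dplyr::n(),
      routes_used = paste(sort(unique(.data$route)), collapse = ","),
      first_admin = min(.data$admin_time),
      last_admin = max(.data$admin_time),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$date)
}

#' Classify calendar days as absolute overdoses
#'
#' Bands are half-open with strict lower edges: no finding at exactly
#' 4000 mg; `abs_4_to_5g` on (4000, 5000] (so exactly 5 g is in the band);
#' `abs_over_5g` on (5000, 6000]; `abs_over_6g` above 6000 mg.
#'
#' @param daily_doses Output of [calendar_day_totals()].
#' @param thresholds A [dose_thresholds()] object.
#' @return Findings tibble (`patient_id`, `date`, `kind`, `total_mg`, ...).
#' @export
classify_absolute <- function(daily_doses, thresholds = dose_thresholds()) {
  daily_doses |>
    dplyr::filter(.data$total_mg > thresholds$abs_daily_mg) |>
    dplyr::mutate(
      kind = dplyr::case_when(
        .data$total_mg > 6000 ~ "abs_over_6g",
        .data$total_mg > thresholds$high_daily_mg ~ "abs_over_5g",
        TRUE ~ "abs_4_to_5g"
      ),
      mg_per_kg = NA_real_,
      weight_used_kg = NA_real_
    ) |>
    dplyr::select("patient_id", "date", "kind", "total_mg", "mg_per_kg",
                  "weight_used_kg", "n_administrations", "routes_used",
                  "first_admin", "last_admin")
}

#' Classify calendar days as relative (mg/kg) overdoses
#'
#' Retrospective weight selection uses the measurement closest in time to
#' the day's administrations in either direction (represented by the
#' midpoint of the day's first and last dose) - deliberately different
#' from the engine's most-recent-prior rule, and insensitive to stale
#' documentation.  A finding requires `total_mg / weight_kg` strictly
#' above the limit and a weight strictly below 60 kg (heavier patients are
#' counted under the absolute analysis only).  Patients with no weight
#' record at all are excluded and tallied.
#'
#' @param daily_doses Output of [calendar_day_totals()].
#' @param weights Weight tibble.
#' @param thresholds A [dose_thresholds()] object.
#' @return Findings tibble with `kind = "relative"`, `mg_per_kg`,
#'   `weight_used_kg` and `weight_band` (`"under_50"`, `"50_to_60"`);
#'   `attr(., "n_no_weight")` counts patients without any weight record.
#' @export
classify_relative <- function(daily_doses, weights, thresholds = dose_thresholds()) {
  wt <- weights[order(weights$patient_id, weights$measured_at), , drop = FALSE]
  wt_split <- split(wt, wt$patient_id)
  rep_time <- as.numeric(daily_doses$first_admin) / 2 +
    as.numeric(daily_doses$last_admin) / 2
  nearest <- function(pid, t) {
    w <- wt_split[[pid]]
    if (is.null(w)) return(c(NA_real_, NA_real_))
    d <- abs(as.numeric(w$measured_at) - t)
    i <- which.min(d)
    c(w$weight_kg[i], d[i] / 86400)
  }
  picked <- purrr::map2(daily_doses$patient_id, rep_time, nearest)
  dd <- daily_doses |>
    dplyr::mutate(
      weight_used_kg = purrr::map_dbl(picked, 1),
      weight_distance_days = purrr::map_dbl(picked, 2),
      mg_per_kg = .data$total_mg / .data$weight_used_kg
    )
  no_weight_patients <- unique(dd$patient_id[is.na(dd$weight_used_kg)])
  out <- dd |>
    dplyr::filter(
      !is.na(.data$weight_used_kg),
      .data$weight_used_kg < thresholds$rel_validation_weight_kg,
      .data$mg_per_kg > thresholds$rel_daily_mg_per_kg
    ) |>
    dplyr::mutate(
      kind = "relative",
      weight_band = ifelse(.data$weight_used_kg < thresholds$low_weight_kg,
                           "under_50", "50_to_60")
    ) |>
    dplyr::select("patient_id", "date", "kind", "total_mg", "mg_per_kg",
                  "weight_used_kg", "weight_band", "n_administrations",
                  "routes_used", "first_admin", "last_admin")
  attr(out, "n_no_weight") <- length(no_weight_patients)
  out
}

#' Maximal runs of consecutive overdose days
#'
#' @param findings Absolute findings tibble (from [classify_absolute()]).
#' @return Tibble of maximal runs of length two or more with strictly
#'   consecutive dates: `patient_id`, `start_date`, `end_date`, `n_days`,
#'   `daily_mg` (list column).
#' @export
find_consecutive_runs <- function(findings) {
  if (nrow(findings) == 0) {
    return(tibble::tibble(patient_id = character(), start_date = as.Date(character()),
                          end_date = as.Date(character()), n_days = integer(),
                          daily_mg = list()))
  }
  findings |>
    dplyr::distinct(.data$patient_id, .data$date, .data$total_mg) |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$date) > 1))) |>
    dplyr::group_by(.data$patient_id, .data$run) |>
    dplyr::summarise(
      start_date = min(.data$date), end_date = max(.data$date),
      n_days = dplyr::n(), daily_mg = list(.data$total_mg), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_days >= 2) |>
    dplyr::select(-"run")
}

#' Attribute a cause to each absolute overdose day
#'
#' Deterministic decision cascade, first match wins:
#' 1. `iv_to_oral_switch` - the day contains both IV and oral paracetamol
#'    and the route changes from IV to oral within the day;
#' 2. `out_of_schedule` - some administration matches no scheduled order
#'    time (within a tolerance, default 60 min) and no on-demand order
#'    covers it;
#' 3. `duplicate_product` - two or more distinct paracetamol-containing
#'    products were given that day;
#' 4. `other`.
#'
#' The cascade order mirrors the observed frequency ordering of the
#' mechanisms and resolves multi-mechanism days deterministically.
#'
#' @param findings Absolute findings tibble.
#' @param administrations Cleaned administration tibble.
#' @param orders Prescription order tibble.
#' @param tolerance_min Matching tolerance around ordered clock times.
#' @return `findings` with a `cause` column; attribution is total.
#' @export
attribute_causes <- function(findings, administrations, orders, tolerance_min = 60) {
  if (nrow(findings) == 0) return(dplyr::mutate(findings, cause = character(0)))
  adm <- dplyr::mutate(administrations, date = dw_date(.data$admin_time))
  adm_split <- split(adm, adm$patient_id)
  ord_split <- split(orders, orders$patient_id)

  cause_one <- function(pid, day) {
    a <- adm_split[[pid]]
    a <- a[a$date == day, , drop = FALSE]
    a <- a[order(a$admin_time), , drop = FALSE]
    # (1) IV -> oral switch within the day
    if (any(a$route == "iv") && any(a$route == "oral")) {
      first_oral <- min(a$admin_time[a$route == "oral"])
      if (any(a$route == "iv" & a$admin_time < first_oral)) return("iv_to_oral_switch")
    }
    # (2) out-of-schedule dose without an on-demand order covering it
    o <- ord_split[[pid]]
    if (!is.null(o)) {
      o <- o[o$valid_from <= max(a$admin_time) & o$valid_to >= min(a$admin_time), , drop = FALSE]
    }
    slot_times <- function(day, sched) {
      toks <- trimws(strsplit(sched, ";", fixed = TRUE)[[1]])
      toks <- toks[toks != "" & toks != "on_demand"]
      if (length(toks) == 0) return(numeric(0))
      as.numeric(dw_time(paste(format(day, "%Y-%m-%d"), toks)))
    }
    has_on_demand <- !is.null(o) && nrow(o) > 0 && any(grepl("on_demand", o$schedule))
    if (!has_on_demand) {
      slots <- if (is.null(o) || nrow(o) == 0) numeric(0) else {
        # include the neighbouring days' slots so tolerance spans midnight
        unlist(lapply(o$schedule, function(s) {
          c(slot_times(day - 1, s), slot_times(day, s), slot_times(day + 1, s))
        }))
      }
      matched <- vapply(as.numeric(a$admin_time), function(t) {
        length(slots) > 0 && min(abs(slots - t)) <= tolerance_min * 60
      }, logical(1))
      if (any(!matched)) return("out_of_schedule")
    }
    # (3) more than one paracetamol-containing product
    if (length(unique(a$product_id)) >= 2) return("duplicate_product")
    "other"
  }

  findings$cause <- purrr::map2_chr(findings$patient_id, findings$date, cause_one)
  findings
}
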