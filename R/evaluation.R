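# Performance surfaces: detection-rate table (retrospective findings vs
# prospective alerts, matched at patient level), alert-frequency table,
# alert burden, and prevalence arithmetic.  All printed rates use half-up
# rounding at the decimal precision of the original tables.

#' Detection rate as a printed percentage
#'
#' `100 * n_alerted / n_real`, rounded half-up to `decimals` places
#' (1 by default, the precision of the published detection table).
#'
#' @param n_real Number of truly affected patients (from the
#'   retrospective gold standard).
#' @param n_alerted Number of those for whom the agent emitted an alert.
#' @param decimals Decimal places.
#' @return Percentage; `NA` (with warning) when `n_real` is zero.
#' @examples
#' detection_rate(39, 34)   # 87.2
#' detection_rate(2276, 645) # 28.3
#' @export
detection_rate <- function(n_real, n_alerted, decimals = 1) {
  stopifnot(length(n_real) == length(n_alerted))
  if (any(n_real < 0 | n_alerted < 0)) stop("counts must be non-negative")
  if (any(n_alerted > n_real)) {
    stop("n_alerted exceeds n_real: alerted patients must be a subset of real ones")
  }
  out <- rep(NA_real_, length(n_real))
  defined <- n_real > 0
  if (any(!defined)) warning("detection rate undefined where n_real is 0")
  out[defined] <- round_half_up(100 * n_alerted[defined] / n_real[defined], decimals)
  out
}

#' Prevalence as a printed percentage
#'
#' `100 * numerator / denominator`, rounded half-up.
#'
#' @param numerator,denominator Counts.
#' @param decimals Decimal places (default 1).
#' @return Percentage; `NA` (with warning) when the denominator is zero.
#' @examples
#' prevalence(2292, 13196)    # 17.4
#' prevalence(911, 2155, 2)   # 42.27
#' @export
prevalence <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    warning("prevalence undefined for zero denominator")
    out <- rep(NA_real_, max(length(numerator), length(denominator)))
    ok <- denominator > 0
    out[ok] <- round_half_up(100 * numerator[ok] / denominator[ok], decimals)
    return(out)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Alert burden per day and per patient
#'
#' @param n_alerts Total alerts in the period.
#' @param n_days Days in the period.
#' @param n_patients Patients with at least one alert.
#' @param decimals Decimal places (default 0, matching the published
#'   whole-number averages).
#' @return One-row tibble with `alerts_per_day` and `alerts_per_patient`.
#' @examples
#' alert_burden(64921, 365, 8108) # 178 alerts/day, 8 alerts/patient
#' @export
alert_burden <- function(n_alerts, n_days, n_patients, decimals = 0) {
  stopifnot(n_days > 0, n_patients > 0)
  tibble::tibble(
    alerts_per_day = round_half_up(n_alerts / n_days, decimals),
    alerts_per_patient = round_half_up(n_alerts / n_patients, decimals)
  )
}

#' Alert-frequency table
#'
#' Counts, share of all alerts, and distinct alerted patients per
#' category, over one engine run.  All seven categories are listed, with
#' zeros where a category never fired; the empty log yields an empty
#' table.
#'
#' @param alerts A `dw_alerts` tibble.
#' @param decimals Decimal places for the percentage column.
#' @return Tibble of class `dw_freq` with `category`, `label`, `n_alerts`,
#'   `percent_of_all`, `n_patients`.
#' @export
alert_frequency_table <- function(alerts, decimals = 1) {
  if (nrow(alerts) == 0) {
    out <- tibble::tibble(category = character(), label = character(),
                          n_alerts = integer(), percent_of_all = numeric(),
                          n_patients = integer())
    return(structure(out, class = c("dw_freq", class(out))))
  }
  counts <- alerts |>
    dplyr::mutate(category = factor(.data$category, levels = dw_alert_levels)) |>
    dplyr::group_by(.data$category, .drop = FALSE) |>
    dplyr::summarise(n_alerts = dplyr::n(),
                     n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop") |>
    dplyr::mutate(
      category = as.character(.data$category),
      label = unname(dw_alert_labels[.data$category]),
      percent_of_all = round_half_up(100 * .data$n_alerts / sum(.data$n_alerts),
                                     decimals)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_alerts)) |>
    dplyr::select("category", "label", "n_alerts", "percent_of_all", "n_patients")
  out <- structure(counts, class = c("dw_freq", class(counts)))
  attr(out, "n_total_alerts") <- nrow(alerts)
  attr(out, "n_total_patients") <- dplyr::n_distinct(alerts$patient_id)
  out
}

#' Match retrospective findings against prospective alerts
#'
#' Builds the detection-rate table: for each finding category, the number
#' of truly affected patients, the number of those with a matching alert,
#' and the detection rate.  Matching is at patient level (by patient id).
#' Two matching modes:
#' * `"any"` (default) - a patient counts as detected if the agent emitted
#'   *any* alert for them, mirroring matching by patient-case number;
#' * `"category"` - an absolute finding requires an absolute-dose or
#'   short-interval alert (A1/A2/A4); a relative finding requires a
#'   relative-dose alert (A3).
#'
#' @param findings Combined findings tibble: rows from
#'   [classify_absolute()] and [classify_relative()] (bound together; the
#'   `kind` column distinguishes them).  Consecutive-day runs are derived
#'   internally from the absolute findings.
#' @param alerts A `dw_alerts` tibble from the same cohort.
#' @param mode Matching mode, see above.
#' @param decimals Decimal places for rates.
#' @return Tibble of class `dw_detection` with rows `over_5g`,
#'   `band_4_5g`, `consecutive_over_4g`, `relative_under_60kg`,
#'   `relative_under_50kg` and columns `n_real`, `n_alerted`,
#'   `rate_percent`.
#' @export
match_detection <- function(findings, alerts, mode = c("any", "category"),
                            decimals = 1) {
  mode <- match.arg(mode)
  abs_kinds <- c("abs_4_to_5g", "abs_over_5g", "abs_over_6g")
  pts <- function(f) unique(f$patient_id)
  abs_f <- dplyr::filter(findings, .data$kind %in% abs_kinds)
  rel_f <- dplyr::filter(findings, .data$kind == "relative")
  if (!"weight_band" %in% names(rel_f)) rel_f$weight_band <- character(nrow(rel_f))
  runs <- find_consecutive_runs(abs_f)

  real_sets <- list(
    over_5g = pts(dplyr::filter(abs_f, .data$kind %in% c("abs_over_5g", "abs_over_6g"))),
    band_4_5g = pts(dplyr::filter(abs_f, .data$kind == "abs_4_to_5g")),
    consecutive_over_4g = unique(runs$patient_id),
    relative_under_60kg = pts(rel_f),
    relative_under_50kg = pts(dplyr::filter(rel_f, .data$weight_band == "under_50"))
  )
  alert_sets <- if (mode == "any") {
    all_p <- unique(alerts$patient_id)
    list(absolute = all_p, relative = all_p)
  } else {
    list(
      absolute = unique(alerts$patient_id[alerts$category %in% c("A1", "A2", "A4")]),
      relative = unique(alerts$patient_id[alerts$category == "A3"])
    )
  }
  which_set <- c(over_5g = "absolute", band_4_5g = "absolute",
                 consecutive_over_4g = "absolute",
                 relative_under_60kg = "relative", relative_under_50kg = "relative")

  rows <- purrr::imap(real_sets, function(real, nm) {
    hit <- intersect(real, alert_sets[[which_set[[nm]]]])
    tibble::tibble(group = nm, n_real = length(real), n_alerted = length(hit))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(rate_percent = ifelse(
      .data$n_real > 0,
      suppressWarnings(detection_rate(.data$n_real, .data$n_alerted, decimals)),
      NA_real_
    ))
  out <- structure(out, class = c("dw_detection", class(out)))
  attr(out, "mode") <- mode
  out
}
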