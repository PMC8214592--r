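# Pharmacist triage: turns per-patient alert summaries plus risk profiles
# into dose-reduction recommendations, and computes the acceptance rate of
# the submitted recommendations.

dw_reasons <- c("body_weight", "max_dose_24h", "body_weight_and_age",
                "lack_of_documentation", "reserve_dose", "not_scheduled",
                "alcoholism", "age", "drug_interaction",
                "body_weight_and_alcoholism", "other", "over_5g_with_inducer")

#' Recommendation reason taxonomy
#'
#' The closed set of intervention reasons recorded by the validating
#' pharmacist, as snake_case tokens.
#'
#' @return Character vector of the twelve reason codes.
#' @export
recommendation_reasons <- function() dw_reasons

#' Triage alert summaries into pharmacist recommendations
#'
#' Applies the clinical validation rules to each patient's cumulative
#' alert summary:
#' * any absolute-dose alert (A1/A2) yields a recommendation; the reason is
#'   the most specific applicable row of the reason taxonomy (an enzyme
#'   inducer alongside an over-5 g alert, alcoholism, age over 75, another
#'   interacting inducer) falling back to `max_dose_24h`;
#' * a relative-dose alert (A3) is validated only below 60 kg: below 50 kg
#'   a reduction is always recommended (`body_weight`, or the combined
#'   weight-and-age / weight-and-alcoholism reasons when those risk factors
#'   are present); between 50 and 60 kg only in the presence of a
#'   hepatotoxicity risk factor (eGFR < 15 ml/min, chronic alcohol use, a
#'   hepatic enzyme inducer, age over 75, severe hepatic impairment);
#' * a persistent missing-weight alert (A5 spanning at least
#'   `a5_persist_h` hours, default 48, with no weight on file) yields a
#'   documentation recommendation.
#'
#' @param summaries Output of [summarize_alerts()].
#' @param stays Stay tibble (age and risk flags).
#' @param weights Weight tibble; the most recent measurement is the weight
#'   known at triage time.
#' @param thresholds A [dose_thresholds()] object.
#' @param a5_persist_h Hours a missing-weight alert must persist before a
#'   documentation recommendation is made.
#' @return Tibble of recommendations: `patient_id`, `reason`,
#'   `proposed_action`, `created_at`.
#' @export
triage_cohort <- function(summaries, stays, weights,
                          thresholds = dose_thresholds(), a5_persist_h = 48) {
  if (nrow(summaries) == 0) {
    return(tibble::tibble(patient_id = character(), reason = character(),
                          proposed_action = character(),
                          created_at = dw_num_time(numeric(0))))
  }
  latest_wt <- weights |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$measured_at, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", triage_weight_kg = "weight_kg")

  wide <- summaries |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_a1 = any(.data$category == "A1"),
      has_a2 = any(.data$category == "A2"),
      has_a3 = any(.data$category == "A3"),
      has_a5 = any(.data$category == "A5"),
      a5_span_h = ifelse(any(.data$category == "A5"),
                         as.numeric(max(.data$last_fired_at[.data$category == "A5"]) -
                                      min(.data$first_fired_at[.data$category == "A5"]),
                                    units = "hours"),
                         0),
      created_at = max(.data$last_fired_at),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::select(stays, "patient_id", "age_years", "risk_flags"),
                     by = "patient_id") |>
    dplyr::left_join(latest_wt, by = "patient_id")

  triage_one <- function(r) {
    flags <- function(tok) dw_has_token(r$risk_flags %||% "", tok)
    over75 <- !is.na(r$age_years) && r$age_years > 75
    risk <- over75 || flags("chronic_alcohol") || flags("enzyme_inducer") ||
      flags("egfr_below_15") || flags("severe_hepatic_impairment")
    w <- r$triage_weight_kg
    a3_eligible <- isTRUE(r$has_a3) && !is.na(w) &&
      (w < thresholds$low_weight_kg ||
         (w < thresholds$rel_validation_weight_kg && risk))
    reason <- NULL
    if (a3_eligible) {
      reason <- if (over75) "body_weight_and_age"
      else if (flags("chronic_alcohol")) "body_weight_and_alcoholism"
      else "body_weight"
    } else if (isTRUE(r$has_a1) || isTRUE(r$has_a2)) {
      reason <- if (isTRUE(r$has_a1) && flags("enzyme_inducer")) "over_5g_with_inducer"
      else if (flags("chronic_alcohol")) "alcoholism"
      else if (over75) "age"
      else if (flags("enzyme_inducer")) "drug_interaction"
      else "max_dose_24h"
    } else if (isTRUE(r$has_a5) && is.na(w) && r$a5_span_h >= a5_persist_h) {
      reason <- "lack_of_documentation"
    }
    if (is.null(reason)) return(NULL)
    action <- switch(reason,
      lack_of_documentation = "document a current body weight",
      body_weight = ,
      body_weight_and_age = ,
      body_weight_and_alcoholism = "reduce paracetamol to <= 60 mg/kg/day",
      "limit paracetamol to <= 4 g/day and review dosing interval"
    )
    tibble::tibble(patient_id = r$patient_id, reason = reason,
                   proposed_action = action, created_at = r$created_at)
  }

  wide |>
    split(seq_len(nrow(wide))) |>
    purrr::map(triage_one) |>
    dplyr::bind_rows()
}

#' Attach intervention outcomes to recommendations
#'
#' An outcome is `not_assessable` iff the patient was discharged within
#' 24 hours of the recommendation; otherwise it is `accepted` or
#' `rejected` as supplied.
#'
#' @param recommendations Output of [triage_cohort()].
#' @param stays Stay tibble (discharge times).
#' @param accepted Logical vector (recycled) saying whether each
#'   assessable recommendation was accepted.
#' @return Tibble with a `status` column
#'   (`accepted`/`rejected`/`not_assessable`).
#' @export
assess_outcomes <- function(recommendations, stays, accepted = TRUE) {
  out <- recommendations |>
    dplyr::left_join(dplyr::select(stays, "patient_id", "discharge"),
                     by = "patient_id") |>
    dplyr::mutate(
      .acc = rep_len(accepted, dplyr::n()),
      status = dplyr::case_when(
        !is.na(.data$discharge) &
          as.numeric(.data$discharge - .data$created_at, units = "hours") < 24 ~
          "not_assessable",
        .acc ~ "accepted",
        TRUE ~ "rejected"
      )
    ) |>
    dplyr::select(-".acc", -"discharge")
  out
}

#' Acceptance rate of submitted recommendations
#'
#' `100 * accepted / (total - not_assessable)`, rounded half-up (default
#' to whole percent).  Undefined (NA, with a warning) when no outcome is
#' assessable.
#'
#' @param outcomes Tibble with a `status` column as from
#'   [assess_outcomes()].
#' @param decimals Decimal places for rounding.
#' @return Percentage, or `NA` when undefined.
#' @export
acceptance_rate <- function(outcomes, decimals = 0) {
  stopifnot("status" %in% names(outcomes))
  acceptance_rate_counts(
    total = nrow(outcomes),
    accepted = sum(outcomes$status == "accepted"),
    not_assessable = sum(outcomes$status == "not_assessable"),
    decimals = decimals
  )
}

#' @rdname acceptance_rate
#' @param total,accepted,not_assessable Outcome counts.
#' @examples
#' acceptance_rate_counts(532, 368, 61) # 78
#' @export
acceptance_rate_counts <- function(total, accepted, not_assessable = 0, decimals = 0) {
  assessable <- total - not_assessable
  if (assessable <= 0) {
    warning("no assessable outcomes; acceptance rate undefined")
    return(NA_real_)
  }
  if (accepted > assessable) stop("more accepted outcomes than assessable ones")
  round_half_up(100 * accepted / assessable, decimals)
}
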