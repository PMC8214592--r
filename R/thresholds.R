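#' Dose-surveillance thresholds
#'
#' Bundles the numeric limits used throughout the surveillance pipeline.
#' Defaults follow the adult paracetamol SmPC limits and the agent's
#' operating rules: absolute overdose above 4 g/24 h, a high band above
#' 5 g/24 h, relative overdose above 60 mg/kg/24 h, a minimum dosing
#' interval of 4 h for the standard 1 g single dose, a 14-day shelf life
#' for weight documentation, and a 60-minute allowance for records entered
#' ahead of the administration they document.
#'
#' All dose thresholds are strict on the lower side with half-open bands:
#' a day (or window) is an overdose iff it exceeds `abs_daily_mg`; the
#' 4-5 g band is `(abs_daily_mg, high_daily_mg]`, so exactly 5 g falls in
#' the band and exactly 6 g in the `> 5 g` class.
#'
#' @param abs_daily_mg Absolute overdose limit, mg per 24 h / calendar day.
#' @param high_daily_mg Upper edge of the 4-5 g band, mg.
#' @param rel_daily_mg_per_kg Relative overdose limit, mg/kg per 24 h.
#' @param min_interval_h Minimum dosing interval, hours.
#' @param single_dose_mg Standard maximal single dose, mg (the 4-h window
#'   limit: more than this within `min_interval_h` fires the interval alert).
#' @param weight_stale_days Age in days beyond which a weight record is
#'   considered old and the mg/kg ratio is not computed by the agent.
#' @param forward_entry_max_min Maximum minutes a record may be entered
#'   before its administration time.
#' @param adult_age_min Minimum age (years, inclusive) for cohort inclusion.
#' @param rel_validation_weight_kg Weight below which relative overdoses are
#'   clinically validated (kg).
#' @param low_weight_kg Weight below which a dose reduction is always
#'   recommended for a relative overdose (kg).
#' @param plaus_min_mg,plaus_max_mg Plausibility band for a single
#'   administration's paracetamol content, mg; recorded values outside it
#'   are repaired against the prescription order.  The band is a package
#'   convention: the smallest common fraction is a 500 mg half tablet and
#'   2000 mg caps at twice the SmPC single maximum.
#' @return A list of class `dw_thresholds`.
#' @examples
#' dose_thresholds()
#' dose_thresholds(weight_stale_days = 30)
#' @export
dose_thresholds <- function(abs_daily_mg = 4000,
                            high_daily_mg = 5000,
                            rel_daily_mg_per_kg = 60,
                            min_interval_h = 4,
                            single_dose_mg = 1000,
                            weight_stale_days = 14,
                            forward_entry_max_min = 60,
                            adult_age_min = 18,
                            rel_validation_weight_kg = 60,
                            low_weight_kg = 50,
                            plaus_min_mg = 100,
                            plaus_max_mg = 2000) {
  th <- list(
    abs_daily_mg = abs_daily_mg,
    high_daily_mg = high_daily_mg,
    rel_daily_mg_per_kg = rel_daily_mg_per_kg,
    min_interval_h = min_interval_h,
    single_dose_mg = single_dose_mg,
    weight_stale_days = weight_stale_days,
    forward_entry_max_min = forward_entry_max_min,
    adult_age_min = adult_age_min,
    rel_validation_weight_kg = rel_validation_weight_kg,
    low_weight_kg = low_weight_kg,
    plaus_min_mg = plaus_min_mg,
    plaus_max_mg = plaus_max_mg
  )
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("all thresholds must be single positive numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (abs_daily_mg >= high_daily_mg) {
    stop("abs_daily_mg must be below high_daily_mg", call. = FALSE)
  }
  if (plaus_min_mg >= plaus_max_mg) {
    stop("plaus_min_mg must be below plaus_max_mg", call. = FALSE)
  }
  structure(th, class = "dw_thresholds")
}

#' Alert-engine configuration
#'
#' @param poll_interval_min Minutes between polls of the administration
#'   stream (the production agent polled every 5 minutes).
#' @param forward_dated_policy How the engine treats records entered before
#'   the documented administration time:
#'   * `"skip_permanently"` (default) - a record whose administration time
#'     lies beyond the tick at which it is first seen is never added to the
#'     cumulative dose: the legacy blind spot behind the low 4-5 g band
#'     detection rate.
#'   * `"defer_until_due"` - such a record is evaluated (and counted) from
#'     the first tick at or after its administration time.
#'   * `"include"` - all records count; models a corrected engine.
#' @param display_policy `"legacy_overshadow"` (a short-interval alert
#'   suppresses same-tick 4-5 g and mg/kg alerts from display) or
#'   `"show_all"`.
#' @param thresholds A [dose_thresholds()] object.
#' @return A list of class `dw_engine_config`.
#' @examples
#' engine_config(forward_dated_policy = "include", display_policy = "show_all")
#' @export
engine_config <- function(poll_interval_min = 5,
                          forward_dated_policy = c("skip_permanently", "defer_until_due", "include"),
                          display_policy = c("legacy_overshadow", "show_all"),
                          thresholds = dose_thresholds()) {
  forward_dated_policy <- match.arg(forward_dated_policy)
  display_policy <- match.arg(display_policy)
  stopifnot(is.numeric(poll_interval_min), length(poll_interval_min) == 1,
            poll_interval_min >= 1)
  stopifnot(inherits(thresholds, "dw_thresholds"))
  structure(
    list(
      poll_interval_min = poll_interval_min,
      forward_dated_policy = forward_dated_policy,
      display_policy = display_policy,
      thresholds = thresholds
    ),
    class = "dw_engine_config"
  )
}

# The seven alert categories, in display order.
dw_alert_levels <- c("A0", "A1", "A2", "A3", "A4", "A5", "A5a")

dw_alert_labels <- c(
  A0 = "dose not calculable",
  A1 = "over 5 g/24 h",
  A2 = "4-5 g/24 h",
  A3 = "over 60 mg/kg/24 h",
  A4 = "interval < 4 h",
  A5 = "no weight record",
  A5a = "old weight record"
)

#' Alert category codes
#'
#' The seven alert categories emitted by the surveillance engine, in
#' canonical order: `A0` dose not calculable, `A1` over 5 g/24 h, `A2`
#' 4-5 g/24 h, `A3` over 60 mg/kg/24 h, `A4` interval < 4 h, `A5` no
#' weight record, `A5a` old weight record.
#'
#' @return A character vector of the seven category codes.
#' @examples
#' alert_categories()
#' @export
alert_categories <- function() dw_alert_levels
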