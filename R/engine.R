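# The prospective alert engine: polls the administration stream on a fixed
# tick grid and evaluates every administration record once, emitting
# categorized alerts.
#
# Windows are half-open on the left: the 24 h window at time t is
# (t - 24 h, t] and includes the triggering dose itself.  A dose exactly
# 24 h old is excluded.

#' Rolling 24-hour cumulative paracetamol dose
#'
#' Sum of normalized doses with administration time in the half-open
#' window `(t - 24 h, t]`, under a forward-dated-record policy:
#' * `"include"` - every record counts;
#' * `"skip_permanently"` - a record whose administration time exceeded the
#'   poll tick at which it was first seen (it was documented in advance) is
#'   permanently excluded from the sum;
#' * `"defer_until_due"` - forward-dated records count from their
#'   administration time onward (equivalent to `include` for a window
#'   ending at or after the administration time).
#'
#' @param history Tibble of one patient's administrations with `admin_time`,
#'   `entry_time` and `dose_mg` columns.
#' @param t Timestamp at which the window ends.
#' @param policy Forward-dated-record policy (see above).
#' @param poll_interval_min Poll interval in minutes used to reconstruct
#'   the tick grid for `skip_permanently`.
#' @param origin Start of the tick grid; defaults to the earliest entry
#'   time in `history`, floored to the minute.
#' @return Dose in mg (scalar).
#' @examples
#' h <- tibble::tibble(
#'   admin_time = as.POSIXct("2017-03-01 06:00", tz = "UTC") + 3600 * c(0, 6, 12),
#'   entry_time = as.POSIXct("2017-03-01 06:02", tz = "UTC") + 3600 * c(0, 6, 12),
#'   dose_mg = 1000
#' )
#' rolling_dose_24h(h, as.POSIXct("2017-03-01 18:00", tz = "UTC"))
#' @export
rolling_dose_24h <- function(history, t,
                             policy = c("include", "skip_permanently", "defer_until_due"),
                             poll_interval_min = 5, origin = NULL) {
  policy <- match.arg(policy)
  if (nrow(history) == 0) return(0)
  t <- dw_time(t)
  skip <- dw_forward_flags(history, policy, poll_interval_min, origin)
  keep <- !skip & !is.na(history$dose_mg) &
    history$admin_time > t - 86400 & history$admin_time <= t
  sum(history$dose_mg[keep])
}

# TRUE for records permanently excluded under skip_permanently
dw_forward_flags <- function(history, policy, poll_interval_min = 5, origin = NULL) {
  if (policy != "skip_permanently") return(rep(FALSE, nrow(history)))
  poll <- poll_interval_min * 60
  origin <- as.numeric(floor_minute(origin %||% min(history$entry_time)))
  en <- as.numeric(history$entry_time)
  tick_seen <- origin + ceiling(pmax(en - origin, 0) / poll) * poll
  as.numeric(history$admin_time) > tick_seen
}

#' Minutes since the previous administered dose
#'
#' @param history Tibble of one patient's administrations (`admin_time`).
#' @param t Administration time of the current dose.
#' @return Minutes between `t` and the immediately preceding dose with a
#'   strictly earlier administration time, or `NA` for the first dose.
#' @export
interval_since_last <- function(history, t) {
  t <- as.numeric(dw_time(t))
  prev <- as.numeric(history$admin_time)
  prev <- prev[prev < t]
  if (length(prev) == 0) return(NA_real_)
  (t - max(prev)) / 60
}

#' Weight-based relative dose at a time point
#'
#' Uses the most recent weight measured at or before `t`.  If none exists
#' the status is `no_weight`; if the most recent one is older than the
#' stale limit (default 14 days) the status is `old_weight` and the mg/kg
#' ratio is deliberately not computed - the legacy agent behavior that
#' blinds it to relative overdoses in patients with stale documentation.
#'
#' @param window_mg Rolling 24-h dose in mg at `t`.
#' @param t Evaluation time.
#' @param weights Tibble of the patient's weight records (`measured_at`,
#'   `weight_kg`).
#' @param thresholds A [dose_thresholds()] object.
#' @return List with `status` (`"ok"`, `"no_weight"`, `"old_weight"`),
#'   `mg_per_kg`, `weight_kg` and `weight_age_days` (`NA` where not
#'   applicable; the weight itself is reported alongside an `old_weight`
#'   status so a reviewer can still see it).
#' @export
relative_dose <- function(window_mg, t, weights, thresholds = dose_thresholds()) {
  t <- as.numeric(dw_time(t))
  w <- weights[as.numeric(weights$measured_at) <= t, , drop = FALSE]
  if (nrow(w) == 0) {
    return(list(status = "no_weight", mg_per_kg = NA_real_,
                weight_kg = NA_real_, weight_age_days = NA_real_))
  }
  i <- which.max(as.numeric(w$measured_at))
  age_days <- (t - as.numeric(w$measured_at[i])) / 86400
  if (age_days > thresholds$weight_stale_days) {
    return(list(status = "old_weight", mg_per_kg = NA_real_,
                weight_kg = w$weight_kg[i], weight_age_days = age_days))
  }
  list(status = "ok", mg_per_kg = window_mg / w$weight_kg[i],
       weight_kg = w$weight_kg[i], weight_age_days = age_days)
}

#' Classify one evaluated administration into alert categories
#'
#' Applies the category rules with strict lower bounds and half-open
#' bands: A1 iff the 24-h window exceeds 5000 mg, A2 iff it lies in
#' (4000, 5000], A3 iff the mg/kg ratio exceeds 60, A4 iff the trailing
#' 4-h window exceeds 1000 mg (which reduces to the interval-under-4-h
#' check for standard 1 g dosing and generalizes it to split doses),
#' A5/A5a passed through from the weight lookup, and A0 alone when the
#' dose could not be normalized.  Several categories may co-fire.
#'
#' @param window24_mg,window4_mg Trailing 24-h and 4-h cumulative doses, mg.
#' @param rel Result of [relative_dose()].
#' @param thresholds A [dose_thresholds()] object.
#' @param dose_ok `FALSE` when the record's dose could not be normalized.
#' @return Character vector of fired category codes (possibly empty).
#' @examples
#' classify_administration(5000, 1000, list(status = "ok", mg_per_kg = 50))
#' @export
classify_administration <- function(window24_mg, window4_mg, rel,
                                    thresholds = dose_thresholds(),
                                    dose_ok = TRUE) {
  if (!dose_ok) return("A0")
  cats <- character(0)
  if (window24_mg > thresholds$high_daily_mg) cats <- c(cats, "A1")
  if (window24_mg > thresholds$abs_daily_mg &&
      window24_mg <= thresholds$high_daily_mg) cats <- c(cats, "A2")
  if (identical(rel$status, "ok") && !is.na(rel$mg_per_kg) &&
      rel$mg_per_kg > thresholds$rel_daily_mg_per_kg) cats <- c(cats, "A3")
  if (window4_mg > thresholds$single_dose_mg) cats <- c(cats, "A4")
  if (identical(rel$status, "no_weight")) cats <- c(cats, "A5")
  if (identical(rel$status, "old_weight")) cats <- c(cats, "A5a")
  cats
}

#' Run the polling alert engine over an administration stream
#'
#' Simulates the production agent: poll ticks at fixed multiples of the
#' poll interval from the start of the stream; each record is evaluated
#' exactly once, at the first tick at or after its entry time (or, under
#' `defer_until_due`, at or after its administration time if that is
#' later).  For every evaluated record the engine computes the trailing
#' 24-h and 4-h cumulative doses, the interval since the previous dose and
#' the weight-based relative dose, then emits one alert row per fired
#' category.  Cumulative doses are computed over the patient's full
#' (policy-filtered) stream, so results are deterministic and independent
#' of record entry latency; the forward-dated blind spot is modeled
#' entirely by the `skip_permanently` policy.
#'
#' @param administrations Cleaned administration tibble with a `dose_mg`
#'   column (see [clean_emar()] / [normalize_doses()]).
#' @param weights Weight tibble.
#' @param stays Stay tibble (used to sanity-check patient ids).
#' @param config An [engine_config()] object.
#' @return Tibble of class `dw_alerts`, one row per alert:
#'   `patient_id`, `category`, `fired_at`, `trigger_record_id`,
#'   `window_dose_mg`, `mg_per_kg`, `interval_minutes`, `weight_used_kg`,
#'   `weight_age_days`, ordered by tick.
#' @examples
#' cfg <- sim_config(n_patients = 20, seed = 7)
#' tabs <- generate_cohort(cfg)
#' adm <- clean_emar(tabs)$administrations
#' alerts <- run_engine(adm, tabs$weights, tabs$stays,
#'                      engine_config(forward_dated_policy = "include"))
#' summarize_alerts(alerts)
#' @export
run_engine <- function(administrations, weights, stays, config = engine_config()) {
  if (!"dose_mg" %in% names(administrations)) {
    stop("administrations must carry a 'dose_mg' column; ",
         "run normalize_doses() or clean_emar() first", call. = FALSE)
  }
  empty <- tibble::tibble(
    patient_id = character(), category = character(),
    fired_at = dw_num_time(numeric(0)), trigger_record_id = character(),
    window_dose_mg = numeric(), mg_per_kg = numeric(),
    interval_minutes = numeric(), weight_used_kg = numeric(),
    weight_age_days = numeric()
  )
  if (nrow(administrations) == 0) return(structure(empty, class = c("dw_alerts", class(empty))))

  th <- config$thresholds
  poll <- config$poll_interval_min * 60
  origin <- as.numeric(floor_minute(min(administrations$entry_time)))
  en <- as.numeric(administrations$entry_time)
  an <- as.numeric(administrations$admin_time)
  tick_seen <- origin + ceiling(pmax(en - origin, 0) / poll) * poll
  eval_num <- switch(config$forward_dated_policy,
    defer_until_due = origin + ceiling(pmax(pmax(en, an) - origin, 0) / poll) * poll,
    tick_seen
  )
  flagged <- an > tick_seen
  contributes <- !is.na(administrations$dose_mg) &
    !(config$forward_dated_policy == "skip_permanently" & flagged)

  df <- administrations |>
    dplyr::mutate(.an = an, .eval = eval_num, .w = ifelse(contributes, .data$dose_mg, 0),
                  .dose_ok = !is.na(.data$dose_mg))
  wt_by_patient <- split(weights[order(weights$measured_at), , drop = FALSE],
                         weights$patient_id[order(weights$measured_at)])

  eval_one_patient <- function(p) {
    p <- p[order(p$.an, p$entry_time, p$record_id), , drop = FALSE]
    tt <- p$.an
    cw <- c(0, cumsum(p$.w)) # padded so a zero index means "nothing in window"
    hi <- findInterval(tt, tt)
    lo24 <- findInterval(tt - 86400, tt)
    lo4 <- findInterval(tt - 14400, tt)
    w24 <- cw[hi + 1] - cw[lo24 + 1]
    w4 <- cw[hi + 1] - cw[lo4 + 1]
    prev <- findInterval(tt - 30, tt) # strictly earlier at minute resolution
    prev_t <- c(NA_real_, tt)[prev + 1]
    interval_min <- (tt - prev_t) / 60

    wt <- wt_by_patient[[p$patient_id[1]]]
    wn <- if (is.null(wt)) numeric(0) else as.numeric(wt$measured_at)
    wv <- if (is.null(wt)) numeric(0) else wt$weight_kg
    k <- findInterval(p$.eval, wn)
    has_w <- k > 0
    weight_kg <- ifelse(has_w, wv[pmax(k, 1)], NA_real_)
    age_days <- ifelse(has_w, (p$.eval - wn[pmax(k, 1)]) / 86400, NA_real_)
    old <- has_w & !is.na(age_days) & age_days > th$weight_stale_days
    ratio <- ifelse(has_w & !old, w24 / weight_kg, NA_real_)

    fire <- list(
      A0 = !p$.dose_ok,
      A1 = p$.dose_ok & w24 > th$high_daily_mg,
      A2 = p$.dose_ok & w24 > th$abs_daily_mg & w24 <= th$high_daily_mg,
      A3 = p$.dose_ok & !is.na(ratio) & ratio > th$rel_daily_mg_per_kg,
      A4 = p$.dose_ok & w4 > th$single_dose_mg,
      A5 = p$.dose_ok & !has_w,
      A5a = p$.dose_ok & old
    )
    rows <- lapply(names(fire), function(cat) {
      idx <- which(fire[[cat]])
      if (length(idx) == 0) return(NULL)
      tibble::tibble(
        patient_id = p$patient_id[idx],
        category = cat,
        fired_at = dw_num_time(p$.eval[idx]),
        trigger_record_id = p$record_id[idx],
        window_dose_mg = if (cat %in% c("A1", "A2", "A3", "A4")) w24[idx] else NA_real_,
        mg_per_kg = if (cat == "A3") ratio[idx] else NA_real_,
        interval_minutes = if (cat == "A4") interval_min[idx] else NA_real_,
        weight_used_kg = if (cat %in% c("A3", "A5a")) weight_kg[idx] else NA_real_,
        weight_age_days = if (cat %in% c("A3", "A5a")) age_days[idx] else NA_real_
      )
    })
    dplyr::bind_rows(rows)
  }

  alerts <- df |>
    split(df$patient_id) |>
    purrr::map(eval_one_patient) |>
    dplyr::bind_rows()
  if (nrow(alerts) == 0) return(structure(empty, class = c("dw_alerts", class(empty))))
  alerts <- alerts |>
    dplyr::mutate(category = factor(.data$category, levels = dw_alert_levels)) |>
    dplyr::arrange(.data$fired_at, .data$patient_id, .data$trigger_record_id,
                   .data$category) |>
    dplyr::mutate(category = as.character(.data$category))
  structure(alerts, class = c("dw_alerts", class(empty)))
}

#' Apply a display policy to an alert log
#'
#' Under the legacy policy, whenever a short-interval alert (A4) fires for
#' a patient at a tick, any 4-5 g (A2) or mg/kg (A3) alert for that
#' patient at the same tick is suppressed from the displayed set - the
#' overshadowing behavior of the original agent.  The raw log is
#' unaffected; `show_all` is the identity.  A1 is never suppressed.
#'
#' @param alerts A `dw_alerts` tibble from [run_engine()].
#' @param policy `"legacy_overshadow"` or `"show_all"`.
#' @return The displayed subset, same structure as `alerts`.
#' @export
apply_display_policy <- function(alerts, policy = c("legacy_overshadow", "show_all")) {
  policy <- match.arg(policy)
  if (policy == "show_all" || nrow(alerts) == 0) return(alerts)
  a4 <- dplyr::filter(alerts, .data$category == "A4") |>
    dplyr::distinct(.data$patient_id, .data$fired_at)
  shadowed <- dplyr::semi_join(
    dplyr::filter(alerts, .data$category %in% c("A2", "A3")),
    a4, by = c("patient_id", "fired_at")
  )
  dplyr::anti_join(
    alerts,
    shadowed,
    by = c("patient_id", "category", "fired_at", "trigger_record_id")
  )
}

#' Summarize alerts patient by patient
#'
#' @param alerts A `dw_alerts` tibble.
#' @return Tibble with one row per (patient, category): `n_alerts`,
#'   `first_fired_at`, `last_fired_at`.  Counts total to the number of
#'   alert rows.
#' @export
summarize_alerts <- function(alerts) {
  if (nrow(alerts) == 0) {
    return(tibble::tibble(patient_id = character(), category = character(),
                          n_alerts = integer(),
                          first_fired_at = dw_num_time(numeric(0)),
                          last_fired_at = dw_num_time(numeric(0))))
  }
  alerts |>
    dplyr::group_by(.data$patient_id, .data$category) |>
    dplyr::summarise(
      n_alerts = dplyr::n(),
      first_fired_at = min(.data$fired_at),
      last_fired_at = max(.data$fired_at),
      .groups = "drop"
    )
}
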