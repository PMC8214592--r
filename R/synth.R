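# Seedable synthetic inpatient cohort generator.
#
# Emulates the statistical structure of an adult inpatient paracetamol
# cohort: mostly-oral administrations, a weight distribution with explicit
# under-50 kg and 50-60 kg components, missing and stale weight
# documentation, forward-dated record entry, and injected overdose days
# of three mechanisms (IV-to-oral switch, out-of-schedule night dose,
# duplicate product) with ground-truth labels.
#
# Baseline dosing is drawn from a restricted grammar (1 g q6h/q8h/q12h and
# 0.5 g q6h at fixed clock slots), which keeps every non-injected calendar
# day provably at or below 4 g: retrospective findings on generator output
# occur exactly on the injected days.

dw_sim_slots <- list(
  q6a = c(5, 11, 17, 23),
  q6b = c(2, 8, 14, 20),
  q8 = c(6, 14, 22),
  q12 = c(8, 20)
)

#' Built-in paracetamol product catalog
#'
#' Six synthetic commercial preparations: 500 mg and 1000 mg tablets, a
#' 10 mg/ml infusion solution, 500 mg and 1000 mg suppositories, and a
#' 500 mg/tablet combination product.
#'
#' @return Catalog tibble (`product_id`, `paracetamol_mg_per_unit`,
#'   `unit_kind`, `is_combination`).
#' @export
paracetamol_catalog <- function() {
  tibble::tibble(
    product_id = c("tab500", "tab1000", "ivsol10", "supp500", "supp1000", "comb500"),
    paracetamol_mg_per_unit = c(500, 1000, 10, 500, 1000, 500),
    unit_kind = c("tablet", "tablet", "ml", "tablet", "tablet", "tablet"),
    is_combination = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the cohort structure of the study setting: 84.2%
#' oral / 15.8% IV / 0.01% rectal administrations; 4.31% of weighed
#' patients under 50 kg and 17.71% under 60 kg; 7.8% of patients without
#' any weight record; overdose days injected for 17.4% of patients with a
#' cause mix of 87.9% IV-to-oral switch, 8.7% out-of-schedule dose and
#' 2.9% duplicate product.  Half of the injected route-switch days total
#' 6 g and half 5 g, giving balanced coverage of the two absolute-overdose
#' severity bands.
#'
#' @param n_patients Number of patients.
#' @param start_date,end_date Study window (admissions leave room for the
#'   longest stay).
#' @param route_mix Named probabilities for `oral`, `iv`, `rectal`
#'   administration routes (normalized internally; applies per baseline
#'   dose - injected mechanism days have mechanism-determined routes).
#' @param weight_mass_under_50,weight_mass_50_60 Probability mass of the
#'   under-50 kg and 50-60 kg weight components.
#' @param missing_weight_prob Probability a patient has no weight record.
#' @param stale_weight_prob Probability a documented weight predates
#'   admission by 15-60 days (stale with respect to all administrations).
#' @param overdose_day_rate Probability an eligible (adult, consenting)
#'   patient receives one injected overdose day.
#' @param cause_mix Named probabilities over the three injected mechanisms
#'   (normalized internally; the route-switch mass is dropped when the IV
#'   route probability is zero, since no switch can occur).
#' @param high_dose_frac Fraction of route-switch days totalling 6 g
#'   rather than 5 g.
#' @param forward_dating_prob Probability per patient-day that one
#'   administration is documented 1-60 minutes in advance.
#' @param forward_dating_prob_overdose Same, for injected overdose days
#'   (`NULL` = same as `forward_dating_prob`).
#' @param forward_max_advance_min Maximum advance in minutes.
#' @param prob_age_over_75 Probability a patient is older than 75.
#' @param risk_flag_prev Named prevalences of the four hepatotoxicity risk
#'   flags.
#' @param consent_prob Probability of general consent.
#' @param seed Mandatory integer seed; all randomness flows from it
#'   through named substreams (cohort, injection, schedule, entry).
#' @return A list of class `dw_sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       start_date = as.Date("2017-01-01"),
                       end_date = as.Date("2017-12-31"),
                       route_mix = c(oral = 0.842, iv = 0.158, rectal = 0.0001),
                       weight_mass_under_50 = 0.0431,
                       weight_mass_50_60 = 0.134,
                       missing_weight_prob = 0.078,
                       stale_weight_prob = 0.15,
                       overdose_day_rate = 0.174,
                       cause_mix = c(iv_to_oral_switch = 0.879,
                                     out_of_schedule = 0.087,
                                     duplicate_product = 0.029),
                       high_dose_frac = 0.5,
                       forward_dating_prob = 0.1,
                       forward_dating_prob_overdose = NULL,
                       forward_max_advance_min = 60,
                       prob_age_over_75 = 0.3,
                       risk_flag_prev = c(chronic_alcohol = 0.05,
                                          enzyme_inducer = 0.002,
                                          egfr_below_15 = 0.02,
                                          severe_hepatic_impairment = 0.01),
                       consent_prob = 0.995,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  stopifnot(n_patients >= 0, length(route_mix) == 3,
            all(route_mix >= 0), sum(route_mix) > 0,
            weight_mass_under_50 + weight_mass_50_60 <= 1,
            overdose_day_rate >= 0, overdose_day_rate <= 1,
            all(cause_mix >= 0), high_dose_frac >= 0, high_dose_frac <= 1,
            forward_dating_prob >= 0, forward_dating_prob <= 1,
            forward_max_advance_min >= 1)
  structure(list(
    n_patients = n_patients, start_date = start_date, end_date = end_date,
    route_mix = route_mix / sum(route_mix),
    weight_mass_under_50 = weight_mass_under_50,
    weight_mass_50_60 = weight_mass_50_60,
    missing_weight_prob = missing_weight_prob,
    stale_weight_prob = stale_weight_prob,
    overdose_day_rate = overdose_day_rate,
    cause_mix = cause_mix,
    high_dose_frac = high_dose_frac,
    forward_dating_prob = forward_dating_prob,
    forward_dating_prob_overdose = forward_dating_prob_overdose %||% forward_dating_prob,
    forward_max_advance_min = forward_max_advance_min,
    prob_age_over_75 = prob_age_over_75,
    risk_flag_prev = risk_flag_prev,
    consent_prob = consent_prob,
    seed = as.integer(seed)
  ), class = "dw_sim_config")
}

# named substream seeds, all below 2^31
dw_substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

dw_day_time <- function(date, hours, minutes = 0) {
  dw_time(as.POSIXct(as.numeric(as.POSIXct(paste(format(date), "00:00:00"), tz = .dw_tz)) +
                       hours * 3600 + minutes * 60,
                     origin = "1970-01-01", tz = .dw_tz))
}

dw_admin_row <- function(patient_id, product_id, dose_amount, dose_unit, route,
                         admin_time, schedule_tag = "scheduled") {
  tibble::tibble(patient_id = patient_id, product_id = product_id,
                 dose_amount = dose_amount, dose_unit = dose_unit,
                 route = route, admin_time = admin_time,
                 schedule_tag = schedule_tag)
}

# recorded representation of a baseline dose, given route and mg
dw_pick_product <- function(route, dose_mg) {
  if (route == "oral") {
    if (dose_mg == 1000) {
      pick <- sample(3, 1)
      if (pick == 1) return(list("tab500", 2, "tablet"))
      if (pick == 2) return(list("tab1000", 1, "tablet"))
      return(list("tab500", 1, "g"))
    }
    if (sample(2, 1) == 1) return(list("tab500", 1, "tablet"))
    return(list("tab500", 500, "mg"))
  }
  if (route == "iv") {
    if (dose_mg == 1000) {
      if (sample(2, 1) == 1) return(list("ivsol10", 100, "ml"))
      return(list("ivsol10", 1000, "mg"))
    }
    return(list("ivsol10", 50, "ml"))
  }
  if (dose_mg == 1000) return(list("supp1000", 1, "tablet"))
  list("supp500", 1, "tablet")
}

#' Construct an IV-to-oral switch overdose day
#'
#' IV doses through midday, then an oral schedule started the same day
#' without regard to the IV doses already given: 2 IV + 3 oral 1 g doses
#' (5 g), or 3 IV + 3 oral (6 g) when `high` is `TRUE`.
#'
#' @param patient_id Patient identifier.
#' @param date Calendar date of the switch.
#' @param high Generate the 6 g variant.
#' @return Administration rows for the day (no `entry_time` yet).
#' @export
inject_route_switch <- function(patient_id, date, high = FALSE) {
  iv_hours <- if (high) c(2, 6, 12) else c(6, 12)
  dplyr::bind_rows(
    dw_admin_row(patient_id, "ivsol10", 100, "ml", "iv",
                 dw_day_time(date, iv_hours)),
    dw_admin_row(patient_id, "tab500", 2, "tablet", "oral",
                 dw_day_time(date, c(14, 18, 22)))
  )
}

#' Construct an out-of-schedule overdose day
#'
#' A standing 4 x 1 g oral schedule (05/11/17/23 h) plus one unscheduled
#' night dose at 02:00 matching no order slot (5 g total; 6 g when
#' `double` adds a second night dose at 03:00).
#'
#' @param patient_id Patient identifier.
#' @param date Calendar date.
#' @param double Add a second night dose.
#' @return Administration rows for the day.
#' @export
inject_out_of_schedule <- function(patient_id, date, double = FALSE) {
  night_hours <- if (double) c(2, 3) else 2
  dplyr::bind_rows(
    dw_admin_row(patient_id, "tab500", 2, "tablet", "oral",
                 dw_day_time(date, night_hours), schedule_tag = "unscheduled"),
    dw_admin_row(patient_id, "tab500", 2, "tablet", "oral",
                 dw_day_time(date, dw_sim_slots$q6a))
  )
}

# duplicate-product day: scheduled 4 x 1 g plain plus 1 g via a
# combination preparation at the 11:00 slot (5 g total)
inject_duplicate_product <- function(patient_id, date) {
  dplyr::bind_rows(
    dw_admin_row(patient_id, "tab500", 2, "tablet", "oral",
                 dw_day_time(date, dw_sim_slots$q6a)),
    dw_admin_row(patient_id, "comb500", 2, "tablet", "oral",
                 dw_day_time(date, 11), schedule_tag = "unscheduled")
  )
}

#' Forward-date record entry
#'
#' For each patient-day selected with probability `prob`, one
#' administration record is documented in advance: its entry time is moved
#' to 1 to `max_advance_min` minutes (uniform, whole minutes) before the
#' administration time.  All other records keep an entry time at or after
#' their administration time.
#'
#' @param administrations Administration tibble with `entry_time`.
#' @param prob Per patient-day selection probability.
#' @param max_advance_min Maximum advance, minutes (capped at the 60-min
#'   allowance of the eMAR dialect by default).
#' @return The tibble with modified `entry_time` for selected records.
#' @export
inject_forward_dating <- function(administrations, prob, max_advance_min = 60) {
  if (prob <= 0 || nrow(administrations) == 0) return(administrations)
  day_key <- paste(administrations$patient_id, dw_date(administrations$admin_time))
  days <- unique(day_key)
  hit_days <- days[runif(length(days)) < prob]
  for (d in hit_days) {
    idx <- which(day_key == d)
    i <- if (length(idx) == 1) idx else sample(idx, 1)
    advance <- max(1, round(runif(1, 1, max_advance_min)))
    administrations$entry_time[i] <- administrations$admin_time[i] - advance * 60
  }
  administrations
}

#' Generate a synthetic cohort with ground-truth overdose labels
#'
#' Deterministic given the configuration seed.  Produces the five eMAR
#' tables plus a ground-truth table listing every injected overdose day
#' with its mechanism and intended total; generated administrations on an
#' injected day sum exactly to that total, and non-injected calendar days
#' never exceed 4 g.
#'
#' @param config A [sim_config()] object.
#' @return Named list: `administrations`, `weights`, `stays`, `orders`,
#'   `catalog`, `ground_truth`.
#' @examples
#' tabs <- generate_cohort(sim_config(n_patients = 10, seed = 42))
#' nrow(tabs$ground_truth)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "dw_sim_config"))
  n <- config$n_patients
  catalog <- paracetamol_catalog()
  empty <- list(
    administrations = tibble::tibble(
      record_id = character(), patient_id = character(), product_id = character(),
      dose_amount = numeric(), dose_unit = character(), route = character(),
      admin_time = dw_num_time(numeric(0)), entry_time = dw_num_time(numeric(0)),
      schedule_tag = character()),
    weights = tibble::tibble(patient_id = character(),
                             measured_at = dw_num_time(numeric(0)),
                             weight_kg = numeric()),
    stays = tibble::tibble(patient_id = character(), age_years = integer(),
                           admission = dw_num_time(numeric(0)),
                           discharge = dw_num_time(numeric(0)),
                           risk_flags = character(), general_consent = logical()),
    orders = tibble::tibble(order_id = character(), patient_id = character(),
                            product_id = character(), dose_mg_per_admin = numeric(),
                            schedule = character(), route = character(),
                            valid_from = dw_num_time(numeric(0)),
                            valid_to = dw_num_time(numeric(0))),
    catalog = catalog,
    ground_truth = tibble::tibble(patient_id = character(),
                                  date = as.Date(character()),
                                  mechanism = character(),
                                  intended_total_mg = numeric())
  )
  if (n == 0) return(empty)

  # --- cohort substream: patient-level attributes -------------------------
  set.seed(dw_substream(config$seed, 1))
  patient_id <- sprintf("P%05d", seq_len(n))
  age_years <- ifelse(runif(n) < config$prob_age_over_75,
                      sample(76:95, n, replace = TRUE),
                      sample(18:75, n, replace = TRUE))
  general_consent <- runif(n) < config$consent_prob
  flags <- vapply(seq_len(n), function(i) {
    f <- names(config$risk_flag_prev)[runif(length(config$risk_flag_prev)) <
                                        config$risk_flag_prev]
    paste(f, collapse = ";")
  }, character(1))
  wclass <- sample(c("u50", "b5060", "ge60"), n, replace = TRUE,
                   prob = c(config$weight_mass_under_50, config$weight_mass_50_60,
                            1 - config$weight_mass_under_50 - config$weight_mass_50_60))
  weight_kg <- round(ifelse(wclass == "u50", runif(n, 38, 49.5),
                     ifelse(wclass == "b5060", runif(n, 50, 59.5),
                            pmin(pmax(rnorm(n, 78, 14), 60.5), 180))), 1)
  has_weight <- runif(n) >= config$missing_weight_prob
  stale <- runif(n) < config$stale_weight_prob
  range_days <- as.integer(config$end_date - config$start_date) - 12
  if (range_days < 1) stop("date range too short for the longest stay", call. = FALSE)
  adm_date <- config$start_date + sample(0:range_days, n, replace = TRUE)

  # --- injection substream: who gets an overdose day and of which kind ----
  set.seed(dw_substream(config$seed, 2))
  cause_mix <- config$cause_mix
  if (config$route_mix[["iv"]] == 0) cause_mix[["iv_to_oral_switch"]] <- 0
  eligible <- general_consent & age_years >= 18
  injected <- eligible & runif(n) < config$overdose_day_rate
  if (config$overdose_day_rate > 0 && n > 0 && !any(eligible)) {
    stop("overdose injection requested but no eligible patients", call. = FALSE)
  }
  mechanism <- rep(NA_character_, n)
  if (any(injected)) {
    if (sum(cause_mix) == 0) {
      injected[] <- FALSE
    } else {
      mechanism[injected] <- sample(names(cause_mix), sum(injected),
                                    replace = TRUE, prob = cause_mix / sum(cause_mix))
    }
  }
  high <- injected & mechanism == "iv_to_oral_switch" &
    runif(n) < config$high_dose_frac

  # --- schedule substream: per-patient courses ----------------------------
  set.seed(dw_substream(config$seed, 3))
  grammar <- list(
    list(hours = dw_sim_slots$q6a, dose = 1000),
    list(hours = dw_sim_slots$q6b, dose = 1000),
    list(hours = dw_sim_slots$q8, dose = 1000),
    list(hours = dw_sim_slots$q12, dose = 1000),
    list(hours = dw_sim_slots$q6a, dose = 500)
  )
  admins <- vector("list", n)
  orders <- vector("list", n)
  gt <- vector("list", n)
  discharge <- dw_num_time(rep(NA_real_, n))
  admission <- dw_day_time(adm_date, 10)

  slot_string <- function(hours) paste(sprintf("%02d:00", hours), collapse = ";")

  for (i in seq_len(n)) {
    pid <- patient_id[i]
    d0 <- adm_date[i] + 1 # first full treatment day
    if (isTRUE(injected[i]) && mechanism[i] == "iv_to_oral_switch") {
      inj_date <- d0 + 1
      day_rows <- list(
        dw_admin_row(pid, "ivsol10", 100, "ml", "iv",
                     dw_day_time(d0, dw_sim_slots$q8)),
        inject_route_switch(pid, inj_date, high = high[i]),
        dw_admin_row(pid, "tab500", 2, "tablet", "oral",
                     dw_day_time(inj_date + 1, dw_sim_slots$q8)),
        dw_admin_row(pid, "tab500", 2, "tablet", "oral",
                     dw_day_time(inj_date + 2, dw_sim_slots$q8))
      )
      last_day <- inj_date + 2
      orders[[i]] <- tibble::tibble(
        patient_id = pid, product_id = "ivsol10", dose_mg_per_admin = 1000,
        schedule = slot_string(dw_sim_slots$q8), route = "iv")
      gt[[i]] <- tibble::tibble(patient_id = pid, date = inj_date,
                                mechanism = mechanism[i],
                                intended_total_mg = if (high[i]) 6000 else 5000)
    } else if (isTRUE(injected[i]) && mechanism[i] %in%
                 c("out_of_schedule", "duplicate_product")) {
      len <- sample(3:6, 1)
      inj_off <- if (len == 3) 2L else sample(2:(len - 1), 1)
      inj_date <- d0 + inj_off - 1
      day_rows <- lapply(seq_len(len), function(k) {
        day <- d0 + k - 1
        if (day == inj_date) {
          if (mechanism[i] == "out_of_schedule") inject_out_of_schedule(pid, day)
          else inject_duplicate_product(pid, day)
        } else {
          dw_admin_row(pid, "tab500", 2, "tablet", "oral",
                       dw_day_time(day, dw_sim_slots$q6a))
        }
      })
      last_day <- d0 + len - 1
      orders[[i]] <- tibble::tibble(
        patient_id = pid, product_id = "tab500", dose_mg_per_admin = 1000,
        schedule = slot_string(dw_sim_slots$q6a), route = "oral")
      gt[[i]] <- tibble::tibble(patient_id = pid, date = inj_date,
                                mechanism = mechanism[i], intended_total_mg = 5000)
    } else {
      sched <- grammar[[sample(length(grammar), 1)]]
      len <- sample(2:7, 1)
      day_rows <- lapply(seq_len(len), function(k) {
        day <- d0 + k - 1
        rows <- lapply(sched$hours, function(h) {
          route <- sample(names(config$route_mix), 1, prob = config$route_mix)
          rep_ <- dw_pick_product(route, sched$dose)
          dw_admin_row(pid, rep_[[1]], rep_[[2]], rep_[[3]], route,
                       dw_day_time(day, h))
        })
        dplyr::bind_rows(rows)
      })
      last_day <- d0 + len - 1
      ord <- tibble::tibble(
        patient_id = pid, product_id = "tab500", dose_mg_per_admin = sched$dose,
        schedule = slot_string(sched$hours), route = "oral")
      if (runif(1) < 0.2) {
        ord <- dplyr::bind_rows(ord, tibble::tibble(
          patient_id = pid, product_id = "tab500", dose_mg_per_admin = 1000,
          schedule = "on_demand", route = "oral"))
      }
      orders[[i]] <- ord
    }
    admins[[i]] <- dplyr::bind_rows(day_rows)
    discharge[i] <- dw_day_time(last_day + 1, 10)
  }

  administrations <- dplyr::bind_rows(admins)
  ground_truth <- dplyr::bind_rows(gt)
  if (nrow(ground_truth) == 0) ground_truth <- empty$ground_truth
  orders_tbl <- dplyr::bind_rows(orders)
  orders_tbl <- orders_tbl |>
    dplyr::mutate(order_id = sprintf("O%05d", dplyr::row_number())) |>
    dplyr::left_join(tibble::tibble(patient_id = patient_id,
                                    valid_from = admission, valid_to = discharge),
                     by = "patient_id") |>
    dplyr::select("order_id", "patient_id", "product_id", "dose_mg_per_admin",
                  "schedule", "route", "valid_from", "valid_to")

  # --- entry substream: documentation times -------------------------------
  set.seed(dw_substream(config$seed, 4))
  administrations <- administrations |>
    dplyr::arrange(.data$patient_id, .data$admin_time, .data$product_id) |>
    dplyr::mutate(
      record_id = sprintf("R%06d", dplyr::row_number()),
      entry_time = .data$admin_time + 60 * sample(0:10, dplyr::n(), replace = TRUE)
    )
  inj_key <- paste(ground_truth$patient_id, ground_truth$date)
  day_key <- paste(administrations$patient_id, dw_date(administrations$admin_time))
  on_inj_day <- day_key %in% inj_key
  adm_base <- inject_forward_dating(administrations[!on_inj_day, , drop = FALSE],
                                    config$forward_dating_prob,
                                    config$forward_max_advance_min)
  adm_inj <- inject_forward_dating(administrations[on_inj_day, , drop = FALSE],
                                   config$forward_dating_prob_overdose,
                                   config$forward_max_advance_min)
  administrations <- dplyr::bind_rows(adm_base, adm_inj) |>
    dplyr::arrange(.data$record_id) |>
    dplyr::select("record_id", "patient_id", "product_id", "dose_amount",
                  "dose_unit", "route", "admin_time", "entry_time", "schedule_tag")

  weights <- tibble::tibble(
    patient_id = patient_id,
    measured_at = dplyr::if_else(stale,
                                 admission - 86400 * round(runif(n, 15, 60)),
                                 admission + 4 * 3600),
    weight_kg = weight_kg
  )[has_weight, , drop = FALSE]

  stays <- tibble::tibble(
    patient_id = patient_id, age_years = as.integer(age_years),
    admission = admission, discharge = discharge,
    risk_flags = flags, general_consent = general_consent
  )

  list(administrations = administrations, weights = weights, stays = stays,
       orders = orders_tbl, catalog = catalog, ground_truth = ground_truth)
}
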