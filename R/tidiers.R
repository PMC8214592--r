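# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.dw_detection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a detection report
#'
#' @param x A `dw_detection` object from [match_detection()].
#' @param ... Unused.
#' @return One-row tibble: matching mode, total real/alerted patients over
#'   the table rows, and the pooled detection rate.
#' @export
glance.dw_detection <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode") %||% NA_character_,
    n_groups = nrow(x),
    n_real_total = sum(x$n_real),
    n_alerted_total = sum(x$n_alerted),
    pooled_rate_percent = ifelse(sum(x$n_real) > 0,
                                 round_half_up(100 * sum(x$n_alerted) / sum(x$n_real), 1),
                                 NA_real_)
  )
}

#' @export
tidy.dw_freq <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at an alert-frequency table
#'
#' @param x A `dw_freq` object from [alert_frequency_table()].
#' @param ... Unused.
#' @return One-row tibble with total alerts and total alerted patients.
#' @export
glance.dw_freq <- function(x, ...) {
  tibble::tibble(
    n_total_alerts = attr(x, "n_total_alerts") %||% sum(x$n_alerts),
    n_total_patients = attr(x, "n_total_patients") %||% NA_integer_
  )
}

#' Glance at an alert log
#'
#' @param x A `dw_alerts` tibble from [run_engine()].
#' @param ... Unused.
#' @return One-row tibble: alert count, alerted patients, span of the log.
#' @export
glance.dw_alerts <- function(x, ...) {
  tibble::tibble(
    n_alerts = nrow(x),
    n_patients = dplyr::n_distinct(x$patient_id),
    first_fired_at = if (nrow(x)) min(x$fired_at) else dw_num_time(NA_real_),
    last_fired_at = if (nrow(x)) max(x$fired_at) else dw_num_time(NA_real_)
  )
}

#' Plot a detection report
#'
#' Bar chart of the patient-level detection rate per overdose category,
#' annotated with the alerted/real counts.
#'
#' @param object A `dw_detection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dw_detection <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- factor(df$group, levels = rev(df$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate_percent, y = .data$group)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_alerted, .data$n_real)),
                       hjust = -0.1, size = 3) +
    ggplot2::xlim(0, 110) +
    ggplot2::labs(x = "detection rate (%)", y = NULL,
                  title = "Agent detection rate by overdose category") +
    ggplot2::theme_minimal()
}

#' Plot an alert-frequency table
#'
#' @param object A `dw_freq` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dw_freq <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_alerts, y = .data$label)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent_of_all)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "alerts", y = NULL, title = "Alert frequency by category") +
    ggplot2::theme_minimal()
}

#' Plot an alert log as a daily time series
#'
#' @param object A `dw_alerts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dw_alerts <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(date = as.Date(.data$fired_at, tz = "UTC")) |>
    dplyr::count(.data$date, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$n, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "alerts/day", fill = "category",
                  title = "Daily alert volume by category") +
    ggplot2::theme_minimal()
}
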