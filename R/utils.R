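# Internal helpers shared across modules.
#
# All timestamps in the package are timezone-naive local hospital time,
# represented as POSIXct in UTC at minute resolution; calendar days split
# at local midnight.

.dw_tz <- "UTC"

dw_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- .dw_tz
    return(x)
  }
  as.POSIXct(x, tz = .dw_tz)
}

dw_num_time <- function(secs) {
  as.POSIXct(secs, origin = "1970-01-01", tz = .dw_tz)
}

floor_minute <- function(t) {
  dw_num_time(floor(as.numeric(t) / 60) * 60)
}

dw_date <- function(t) as.Date(t, tz = .dw_tz)

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with halves rounded up, the
#' convention used for all printed percentages and rates in this package
#' (base R's `round()` rounds halves to even).  A tiny epsilon guards
#' against binary representation error in quotients such as `100 * 34/39`.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(100 * 34 / 39, 1) # 87.2
#' round_half_up(0.5, 0)           # 1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# semicolon-joined token set helpers (risk_flags column)
dw_has_token <- function(joined, token) {
  vapply(
    strsplit(ifelse(is.na(joined), "", joined), ";", fixed = TRUE),
    function(tok) token %in% trimws(tok),
    logical(1)
  )
}

dw_abort_missing_cols <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: missing required column%s %s",
      table, if (length(missing) > 1) "s" else "",
      paste0("'", missing, "'", collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
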