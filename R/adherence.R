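# Adherence calendar derivation and dose accounting.

#' Classify one day's dose
#'
#' A day is `"full"` with at least 60 minutes of play, `"half"` with at least
#' 30 but under 60 minutes, and `"none"` below 30 minutes. Thresholds rather
#' than session counts are used so irregular real-world logs remain
#' classifiable; under the prescribed protocol two 30-minute sessions make a
#' full day and one makes a half day.
#'
#' @param session_minutes Numeric vector of session durations (minutes)
#'   played that day; may be empty.
#' @return `"full"`, `"half"` or `"none"`.
#' @examples
#' day_dose_classify(c(30, 30))  # full
#' day_dose_classify(30)         # half
#' day_dose_classify(numeric(0)) # none
#' @export
day_dose_classify <- function(session_minutes) {
  total <- sum(session_minutes)
  if (total >= 60) {
    "full"
  } else if (total >= 30) {
    "half"
  } else {
    "none"
  }
}

#' Build an adherence calendar from dated sessions
#'
#' Aggregates session durations by calendar day over a continuous day range
#' (days without sessions are kept as `"none"`), classifies each day with
#' [day_dose_classify()], and accumulates dose hours. Sessions are assigned
#' to the local calendar day on which they start.
#'
#' @param dates Session start dates (coercible with `as.Date()`).
#' @param durations_min Session durations in minutes (same length).
#' @param first_day,last_day Day range of the calendar; default to the range
#'   of `dates`.
#' @return data.frame `date, class, minutes, cumulative_hours`, one row per
#'   calendar day.
#' @export
adherence_calendar <- function(dates, durations_min,
                               first_day = NULL, last_day = NULL) {
  stopifnot(length(dates) == length(durations_min))
  dates <- as.Date(dates)
  first_day <- as.Date(first_day %||% min(dates))
  last_day <- as.Date(last_day %||% max(dates))
  days <- seq(first_day, last_day, by = "day")
  minutes <- vapply(days, function(d) {
    sum(durations_min[dates == d])
  }, numeric(1))
  cls <- vapply(seq_along(days), function(i) {
    day_dose_classify(minutes[i][minutes[i] > 0])
  }, character(1))
  data.frame(date = as.character(days), class = cls, minutes = minutes,
             cumulative_hours = cumsum(minutes) / 60,
             stringsAsFactors = FALSE)
}

#' Adherence calendar of a simulated study
#'
#' Convenience wrapper building the intervention-block calendar of a
#' [simulate_study()] dataset, spanning every day of the protocol's
#' adherence pattern (including skipped days).
#'
#' @param dataset A `study_dataset`.
#' @return Calendar data.frame as from [adherence_calendar()].
#' @export
study_calendar <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  keep <- vapply(dataset$sessions, function(s) s$phase == "intervention",
                 logical(1))
  iv <- dataset$sessions[keep]
  dates <- vapply(iv, `[[`, character(1), "date")
  durations <- vapply(iv, function(s) s$duration_s / 60, numeric(1))
  first <- dataset$protocol$start_date
  last <- first + length(dataset$protocol$adherence_pattern) - 1
  if (length(dates) == 0) {
    dates <- as.character(first)
    durations <- 0
  }
  adherence_calendar(dates, durations, first_day = first, last_day = last)
}

#' Dose accounting over an adherence calendar
#'
#' Totals the delivered dose and finds the day the dose target was reached.
#'
#' @param calendar Calendar data.frame from [adherence_calendar()].
#' @param target_hours Dose target in hours (default 14).
#' @return List with `total_hours`, `days_elapsed`, `target_met_day` (the
#'   date, or `NA` if the target was never reached), and per-class day
#'   counts `n_full`, `n_half`, `n_none`.
#' @export
dose_accounting <- function(calendar, target_hours = 14) {
  if (is.null(calendar) || nrow(calendar) == 0) {
    stop_domain("calendar must be nonempty")
  }
  met <- which(calendar$cumulative_hours >= target_hours)
  list(
    total_hours = sum(calendar$minutes) / 60,
    days_elapsed = nrow(calendar),
    target_met_day = if (length(met)) calendar$date[met[1]] else NA_character_,
    n_full = sum(calendar$class == "full"),
    n_half = sum(calendar$class == "half"),
    n_none = sum(calendar$class == "none")
  )
}
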