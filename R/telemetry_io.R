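# Readers and writers for the artifact's data: per-attempt event logs with a
# flat metadata sidecar, raw accelerometry CSV with a self-describing header,
# clinical tables, and the adherence calendar. Parsers reject malformed or
# out-of-range input with the offending line number rather than coercing.

#' 3-axis acceleration series
#'
#' Container for one hand's accelerometer recording: an n x 3 matrix of
#' samples in g units at a fixed sampling rate.
#'
#' @param samples Numeric matrix with 3 columns (x, y, z) in g.
#' @param sample_rate Sampling rate in Hz.
#' @param hand `"dominant"` or `"nondominant"`.
#' @param start_time Wall-clock start time as `"YYYY-MM-DD HH:MM:SS"` (or NA).
#' @return Object of class `accel_series`.
#' @export
accel_series <- function(samples, sample_rate, hand = "dominant",
                         start_time = NA_character_) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) {
    stop_domain("accel samples must have 3 columns (x, y, z)")
  }
  if (any(!is.finite(samples))) {
    stop_domain("accel samples contain non-finite values")
  }
  check_scalar(sample_rate, "sample_rate", lo = 1e-9)
  if (!hand %in% c("dominant", "nondominant")) {
    stop_domain("unknown hand label: %s", hand)
  }
  colnames(samples) <- c("x", "y", "z")
  structure(list(samples = samples, sample_rate = sample_rate, hand = hand,
                 start_time = start_time),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %s hand, %d samples @ %g Hz (%.1f s)\n",
              x$hand, nrow(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate))
  invisible(x)
}

#' Down-sample an acceleration series
#'
#' Applies a zero-phase anti-alias low-pass (4th-order Butterworth, cutoff
#' `0.45 * target_rate`, run forward and backward) and then decimates. The
#' target rate must divide the sampling rate.
#'
#' @param series An [accel_series()].
#' @param target_rate Target rate in Hz (default 30).
#' @return An [accel_series()] at `target_rate` with
#'   `ceiling(n * target_rate / sample_rate)` samples.
#' @export
downsample_accel <- function(series, target_rate = 30) {
  stopifnot(inherits(series, "accel_series"))
  check_scalar(target_rate, "target_rate", lo = 1e-9)
  factor <- series$sample_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop_domain("target_rate %g does not divide sample_rate %g",
                target_rate, series$sample_rate)
  }
  factor <- round(factor)
  if (factor == 1) {
    return(series)
  }
  w <- (0.45 * target_rate) / (series$sample_rate / 2)
  bf <- signal::butter(4, w, type = "low")
  filtered <- apply(series$samples, 2, function(col) {
    signal::filtfilt(bf, col)
  })
  keep <- seq(1, nrow(series$samples), by = factor)
  accel_series(filtered[keep, , drop = FALSE], sample_rate = target_rate,
               hand = series$hand, start_time = series$start_time)
}

# ---- event logs -----------------------------------------------------------

event_log_header <- c("timestamp_s", "hand", "outcome", "level", "powerups",
                      "score_after")

#' Write and read session event logs
#'
#' The event log is delimited text with header
#' `timestamp_s,hand,outcome,level,powerups,score_after`, one row per rocket
#' launch. Session metadata (seed, config hash, duration, scores, phase)
#' lives in a flat `key = value` sidecar at `<path>.meta`. Reading a log and
#' its sidecar reconstructs the session record's canonical form (the full
#' game configuration itself is identified by its hash, not embedded).
#'
#' @param record A `session_record`.
#' @param path Event-log file path; the sidecar is written to `<path>.meta`.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `session_record`.
#' @export
write_session_log <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  ev <- record$events
  ev$timestamp_s <- sprintf("%.3f", ev$timestamp_s)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    seed = record$seed,
    config_hash = record$config_hash,
    duration_s = record$duration_s,
    final_score = record$final_score,
    high_score_start = record$high_score_start,
    high_score_end = record$high_score_end,
    boss_completions = record$boss_completions,
    practice_hours_start = record$practice_hours_start,
    phase = record$phase %||% NA_character_,
    date = record$date %||% NA_character_,
    start_time = record$start_time %||% NA_character_,
    session_id = record$session_id %||% NA_character_
  )
  write_flat(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) {
    stop_domain("event log not found: %s", path)
  }
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(header, event_log_header)) {
    stop_domain("parse error in %s line 1: expected header '%s'",
                path, paste(event_log_header, collapse = ","))
  }
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(timestamp_s = "numeric",
                                       hand = "character",
                                       outcome = "character",
                                       level = "integer",
                                       powerups = "character",
                                       score_after = "integer"))
  ev$powerups[is.na(ev$powerups)] <- ""
  bad <- which(!ev$outcome %in% c("hit_robot", "miss", "hit_powerup",
                                  "hit_boss"))
  if (length(bad)) {
    stop_domain("parse error in %s line %d: unknown outcome '%s'",
                path, bad[1] + 1L, ev$outcome[bad[1]])
  }
  if (is.unsorted(ev$timestamp_s)) {
    stop_domain("parse error in %s: timestamps are not nondecreasing", path)
  }
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop_domain("missing metadata sidecar: %s", meta_path)
  }
  meta <- read_flat(meta_path)
  structure(
    list(events = ev,
         seed = as.integer(meta$seed),
         config = NULL,
         config_hash = as.character(meta$config_hash),
         duration_s = as.numeric(meta$duration_s),
         final_score = as.integer(meta$final_score),
         high_score_start = as.integer(meta$high_score_start),
         high_score_end = as.integer(meta$high_score_end),
         boss_completions = as.integer(meta$boss_completions),
         practice_hours_start = as.numeric(meta$practice_hours_start),
         phase = as.character(meta$phase),
         date = as.character(meta$date),
         start_time = as.character(meta$start_time),
         session_id = as.character(meta$session_id)),
    class = "session_record"
  )
}

# ---- raw accelerometry CSV ------------------------------------------------

#' Write and read raw accelerometry CSV
#'
#' Self-describing raw-accelerometry dialect: `#`-prefixed metadata lines
#' (`sample_rate_hz`, `start_time`, `hand`), a `timestamp,x_g,y_g,z_g`
#' column header, then one row per sample.
#'
#' @param series An [accel_series()].
#' @param path File path.
#' @return `write_accel_csv()` returns `path` invisibly; `read_accel_csv()`
#'   returns an [accel_series()].
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_rate_hz=%g", series$sample_rate),
               sprintf("# start_time=%s", series$start_time),
               sprintf("# hand=%s", series$hand),
               "timestamp,x_g,y_g,z_g"), con)
  n <- nrow(series$samples)
  ts <- (seq_len(n) - 1) / series$sample_rate
  lines <- sprintf("%.6f,%.6g,%.6g,%.6g", ts,
                   series$samples[, 1], series$samples[, 2],
                   series$samples[, 3])
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) {
    stop_domain("accel file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", lines[i]), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$sample_rate_hz)) {
    stop_domain("parse error in %s: missing '# sample_rate_hz=' metadata",
                path)
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  if (lines[body_start] != "timestamp,x_g,y_g,z_g") {
    stop_domain("parse error in %s line %d: expected header 'timestamp,x_g,y_g,z_g'",
                path, body_start)
  }
  dat <- utils::read.csv(text = lines[body_start:length(lines)],
                         stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(dat)))) {
    bad <- which(!stats::complete.cases(dat))[1]
    stop_domain("parse error in %s line %d: non-numeric sample",
                path, body_start + bad)
  }
  accel_series(as.matrix(dat[, c("x_g", "y_g", "z_g")]),
               sample_rate = as.numeric(meta$sample_rate_hz),
               hand = meta$hand %||% "dominant",
               start_time = meta$start_time %||% NA_character_)
}

# ---- clinical tables ------------------------------------------------------

#' Read and write a COPM goal table
#'
#' CSV with columns `goal, performance_pre, performance_post,
#' satisfaction_pre, satisfaction_post` (the satisfaction scale is labelled
#' "perception" in some reports); scores must be integers 1..10. Out-of-range
#' rows raise a parse error naming the line.
#'
#' @param path File path.
#' @param table A data.frame in the same layout.
#' @return `read_copm_table()` returns the validated data.frame.
#' @export
read_copm_table <- function(path) {
  if (!file.exists(path)) {
    stop_domain("COPM table not found: %s", path)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("goal", "performance_pre", "performance_post",
            "satisfaction_pre", "satisfaction_post")
  if (!identical(names(dat), need)) {
    stop_domain("parse error in %s line 1: expected header '%s'",
                path, paste(need, collapse = ","))
  }
  for (col in need[-1]) {
    v <- dat[[col]]
    bad <- which(!is.finite(v) | v != round(v) | v < 1 | v > 10)
    if (length(bad)) {
      stop_domain("parse error in %s line %d: %s = %s outside 1..10",
                  path, bad[1] + 1L, col, v[bad[1]])
    }
  }
  dat
}

#' @rdname read_copm_table
#' @export
write_copm_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read clinical phase scores (Box and Blocks / Nine-Hole Peg)
#'
#' CSV with columns `measure, hand, phase, session, value`: `measure` in
#' `BBT` (blocks moved) or `NHPT` (pegs per second), `hand` dominant or
#' nondominant, `phase` baseline/intervention/post. Values must be
#' non-negative.
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_phase_scores <- function(path) {
  if (!file.exists(path)) {
    stop_domain("phase-score table not found: %s", path)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "hand", "phase", "session", "value")
  if (!identical(names(dat), need)) {
    stop_domain("parse error in %s line 1: expected header '%s'",
                path, paste(need, collapse = ","))
  }
  bad <- which(!dat$measure %in% c("BBT", "NHPT"))
  if (length(bad)) {
    stop_domain("parse error in %s line %d: unknown measure '%s'",
                path, bad[1] + 1L, dat$measure[bad[1]])
  }
  bad <- which(!is.finite(dat$value) | dat$value < 0)
  if (length(bad)) {
    stop_domain("parse error in %s line %d: negative or missing value",
                path, bad[1] + 1L)
  }
  dat
}

# ---- adherence calendar CSV ----------------------------------------------

#' Write and read the adherence calendar
#'
#' CSV export `date,class,minutes,cumulative_hours` of an adherence calendar
#' (see [adherence_calendar()]).
#'
#' @param calendar Calendar data.frame.
#' @param path File path.
#' @return `read_calendar_csv()` returns the calendar data.frame.
#' @export
write_calendar_csv <- function(calendar, path) {
  utils::write.csv(calendar[, c("date", "class", "minutes",
                                "cumulative_hours")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calendar_csv
#' @export
read_calendar_csv <- function(path) {
  if (!file.exists(path)) {
    stop_domain("calendar file not found: %s", path)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "class", "minutes", "cumulative_hours")
  if (!identical(names(dat), need)) {
    stop_domain("parse error in %s line 1: expected header '%s'",
                path, paste(need, collapse = ","))
  }
  bad <- which(!dat$class %in% c("full", "half", "none"))
  if (length(bad)) {
    stop_domain("parse error in %s line %d: unknown class '%s'",
                path, bad[1] + 1L, dat$class[bad[1]])
  }
  dat
}
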