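test_that("down-sampling decimates 4:1 and preserves in-band amplitude", {
  s <- sine_series(1, 0.5, rate_hz = 120, seconds = 30)
  expect_identical(nrow(s$samples), 3600L)
  d <- downsample_accel(s, 30)
  expect_identical(nrow(d$samples), 900L)
  expect_identical(d$sample_rate, 30)

  # a 1 Hz tone passes nearly untouched (ignore filter edges)
  core <- d$samples[100:800, 3] - 1
  expect_equal(max(abs(core)), 0.5, tolerance = 0.01)

  # a 20 Hz tone (above the 13.5 Hz cutoff) is strongly attenuated
  hi <- downsample_accel(sine_series(20, 0.5, 120, 30), 30)
  expect_lt(max(abs(hi$samples[100:800, 3] - 1)), 0.05)

  expect_error(downsample_accel(s, 50), "divide")
})

test_that("session logs round-trip through CSV plus sidecar", {
  rec <- run_session(player_policy(stationary_player(0.8)), short_config(),
                     seed = 21, high_score = 50)
  rec$phase <- "baseline"
  rec$date <- "2024-03-11"
  rec$start_time <- "2024-03-11 10:00:00"
  rec$session_id <- "S01_baseline_20240311"
  path <- file.path(withr::local_tempdir(), "s1.csv")
  write_session_log(rec, path)
  back <- read_session_log(path)
  expect_equal(back$events, rec$events)
  for (f in c("seed", "duration_s", "final_score", "high_score_start",
              "high_score_end", "boss_completions", "phase", "date",
              "session_id", "config_hash")) {
    expect_equal(back[[f]], rec[[f]], info = f)
  }
  expect_equal(session_metrics(back), session_metrics(rec))
})

test_that("event-log parsing rejects malformed input", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.csv")
  writeLines(c("time,hand,outcome", "1,dominant,hit_robot"), bad)
  expect_error(read_session_log(bad), "header")

  bad2 <- file.path(td, "bad2.csv")
  writeLines(c("timestamp_s,hand,outcome,level,powerups,score_after",
               "1.0,dominant,exploded,1,,1"), bad2)
  writeLines("seed = 1", paste0(bad2, ".meta"))
  expect_error(read_session_log(bad2), "line 2")
})

test_that("raw accelerometry CSV round-trips with its metadata", {
  s <- sine_series(2, 0.3, rate_hz = 30, seconds = 5)
  path <- file.path(withr::local_tempdir(), "acc.csv")
  write_accel_csv(s, path)
  back <- read_accel_csv(path)
  expect_identical(nrow(back$samples), nrow(s$samples))
  expect_identical(back$sample_rate, 30)
  expect_identical(back$hand, "dominant")
  expect_equal(back$samples, s$samples, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("flat config files round-trip and reject unknown keys", {
  td <- withr::local_tempdir()
  cfg <- game_config(session_cap_s = 600, up_threshold = 0.7)
  p1 <- file.path(td, "game.cfg")
  write_game_config(cfg, p1)
  expect_equal(read_game_config(p1), cfg)

  writeLines(c("session_cap_s = 600", "warp_drive = 1"),
             file.path(td, "odd.cfg"))
  expect_error(read_game_config(file.path(td, "odd.cfg")), "warp_drive")

  pp <- player_params(skill = 1.3, hand_asymmetry = 0.6)
  p2 <- file.path(td, "player.cfg")
  write_player_params(pp, p2)
  expect_equal(read_player_params(p2), pp)

  proto <- study_protocol(adherence_pattern = "FFHNN", session_minutes = 10)
  p3 <- file.path(td, "proto.cfg")
  write_study_protocol(proto, p3)
  back <- read_study_protocol(p3)
  expect_identical(back$adherence_pattern, c("F", "F", "H", "N", "N"))
  expect_equal(back$session_minutes, 10)
  expect_identical(back$start_date, proto$start_date)
})

test_that("COPM tables validate score ranges on read", {
  tab <- read_copm_table(copm_fixture_path())
  expect_identical(nrow(tab), 5L)
  td <- withr::local_tempdir()
  bad <- tab
  bad$performance_post[2] <- 11
  path <- file.path(td, "copm.csv")
  write_copm_table(bad, path)
  expect_error(read_copm_table(path), "line 3")
})

test_that("days classify by dose thresholds", {
  expect_identical(day_dose_classify(c(30, 30)), "full")
  expect_identical(day_dose_classify(30), "half")
  expect_identical(day_dose_classify(numeric(0)), "none")
  expect_identical(day_dose_classify(c(10, 10)), "none")
  expect_identical(day_dose_classify(c(45, 20)), "full")
})

test_that("calendar accounting matches the adherence pattern arithmetic", {
  pattern <- default_adherence_pattern()
  day0 <- as.Date("2024-04-01")
  dates <- character(0)
  durations <- numeric(0)
  for (d in seq_along(pattern)) {
    n <- switch(pattern[d], F = 2, H = 1, N = 0)
    if (n > 0) {
      dates <- c(dates, rep(as.character(day0 + d - 1), n))
      durations <- c(durations, rep(30, n))
    }
  }
  cal <- adherence_calendar(dates, durations, first_day = day0,
                            last_day = day0 + 21)
  acct <- dose_accounting(cal, target_hours = 14)
  expect_identical(acct$days_elapsed, 22L)
  expect_identical(acct$n_full, 11L)
  expect_identical(acct$n_half, 5L)
  expect_identical(acct$n_none, 6L)
  expect_equal(acct$total_hours, 13.5)  # exact arithmetic of 11 + 5/2
  expect_true(is.na(acct$target_met_day))
  expect_true(all(diff(cal$cumulative_hours) >= 0))

  # reaching the target mid-calendar is reported on the first qualifying day
  acct2 <- dose_accounting(cal, target_hours = 10)
  expect_identical(acct2$target_met_day,
                   cal$date[which(cal$cumulative_hours >= 10)[1]])

  # day classes are invariant to session ordering within a day
  perm <- sample(seq_along(dates))
  cal2 <- adherence_calendar(dates[perm], durations[perm], first_day = day0,
                             last_day = day0 + 21)
  expect_identical(cal, cal2)

  none_cal <- adherence_calendar(as.character(day0), 0, first_day = day0,
                                 last_day = day0 + 2)
  acct3 <- dose_accounting(none_cal)
  expect_equal(acct3$total_hours, 0)
  expect_true(is.na(acct3$target_met_day))
  expect_error(dose_accounting(none_cal[0, ]), "nonempty")

  # round-trip through the CSV export
  path <- file.path(withr::local_tempdir(), "cal.csv")
  write_calendar_csv(cal, path)
  expect_equal(read_calendar_csv(path), cal)
})

test_that("clinical phase scores load and validate", {
  tab <- read_phase_scores(system.file("extdata",
                                       "clinical_phase_scores.csv",
                                       package = "habitvr"))
  expect_identical(nrow(tab), 8L)
  expect_setequal(unique(tab$measure), c("BBT", "NHPT"))
  expect_equal(tab$value[tab$measure == "BBT" & tab$hand == "dominant" &
                           tab$phase == "post"], 65)
  td <- withr::local_tempdir()
  bad <- tab
  bad$value[3] <- -1
  path <- file.path(td, "scores.csv")
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_phase_scores(path), "line 4")
})
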