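# Shared fixtures: small configurations keep simulated sessions fast; all
# synthetic signals are built in code.

short_config <- function(...) {
  game_config(session_cap_s = 120, ...)
}

# Player with frozen skill (no learning), used for stationary-behaviour
# properties.
stationary_player <- function(skill, ...) {
  player_params(skill = skill, skill_gain_fast = 0, skill_gain_slow = 0, ...)
}

# Cheap player whose sessions have very few attempts; useful when only the
# session calendar/duration structure matters.
sparse_player <- function() {
  player_params(fire_rate_base = 0.5, fire_rate_gain = 0)
}

copm_fixture_path <- function() {
  system.file("extdata", "copm_goals.csv", package = "habitvr",
              mustWork = TRUE)
}

# Pure sinusoid accelerometry on the z axis (plus gravity), for filter and
# counts checks.
sine_series <- function(freq_hz, amp_g, rate_hz = 120, seconds = 30,
                        gravity = 1) {
  t <- seq(0, seconds - 1 / rate_hz, by = 1 / rate_hz)
  z <- gravity + amp_g * sin(2 * pi * freq_hz * t)
  accel_series(cbind(0, 0, z), sample_rate = rate_hz, hand = "dominant")
}

# A tiny session record built by hand (no engine involved).
manual_session <- function(times, outcomes, duration_s = 60,
                           hands = rep("dominant", length(times))) {
  structure(
    list(events = data.frame(timestamp_s = times, hand = hands,
                             outcome = outcomes,
                             level = rep(1L, length(times)),
                             powerups = rep("", length(times)),
                             score_after = cumsum(outcomes %in%
                               c("hit_robot", "hit_boss")),
                             stringsAsFactors = FALSE),
         seed = 1L, config = NULL, config_hash = "manual",
         duration_s = duration_s,
         final_score = sum(outcomes %in% c("hit_robot", "hit_boss")),
         high_score_start = 0L, high_score_end = 0L,
         boss_completions = 0L, practice_hours_start = 0,
         phase = "baseline", date = "2024-01-01",
         start_time = "2024-01-01 10:00:00", session_id = "manual"),
    class = "session_record"
  )
}
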