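#' Game configuration
#'
#' Builds the full constant set of the headless rocket game: session clock,
#' adaptive-difficulty controller thresholds, level geometry steps, the
#' target-score motivator, boss-battle chain rules and power-up effects.
#'
#' The defaults encode the published design of the home-based bimanual VR
#' game: a 30-minute automatic session cap, five difficulty levels entered at
#' level 1, a +25% target-speed and -10% target-size step per level, a
#' success-rate controller that steps difficulty up above 60% and down below
#' 30%, a target score 5% above the running high score, and a boss that
#' requires 7 hits each within 3 seconds of the previous one.
#'
#' The evaluation window of the difficulty controller is not fully specified
#' by the published design ("the last set of attempts within a specific time
#' frame"); here it is a rolling window over the most recent `eval_window`
#' robot-directed launches restricted to the last `eval_window_span_s`
#' seconds, evaluated after every robot launch once `eval_min_attempts`
#' launches have accumulated, and cleared on every level change so that a new
#' level is judged only on evidence gathered at that level.
#'
#' @param session_cap_s Session length cap in seconds; the game exits
#'   automatically when it is reached (default 1800 s = 30 min).
#' @param up_threshold Windowed success rate above which difficulty increases
#'   (default 0.60).
#' @param down_threshold Windowed success rate below which difficulty
#'   decreases (default 0.30).
#' @param n_levels Number of difficulty levels (default 5).
#' @param speed_step Fractional target-speed increase per level (default 0.25).
#' @param size_step Fractional target-size decrease per level (default 0.10).
#' @param target_score_factor Fractional margin of the target score above the
#'   high score (default 0.05).
#' @param boss_hits_required Chained hits needed to complete the boss
#'   (default 7).
#' @param boss_chain_window_s Maximum seconds between consecutive boss hits
#'   that preserves chain progress (default 3).
#' @param base_target_speed,base_target_size Level-1 target speed and size in
#'   arbitrary consistent units (defaults 1, 1).
#' @param eval_window Number of most recent robot launches the controller may
#'   consider (default 20).
#' @param eval_window_span_s Age limit in seconds on launches in the window
#'   (default 60).
#' @param eval_min_attempts Minimum launches in the window before any
#'   evaluation (default 5).
#' @param boss_size_factor,boss_speed_factor Boss size and speed relative to
#'   the current robot target (defaults 3 and 1: a large target moving only
#'   horizontally at the level speed).
#' @param allow_boss_repeat Whether the boss can be unlocked again in the same
#'   session after completion, once the recomputed target score is beaten
#'   (default TRUE).
#' @param powerup_spawn_per_min Mean number of power-up orbs spawned per
#'   minute (Poisson; default 1).
#' @param powerup_size_factor Power-up orb size relative to the current robot
#'   size; orbs are stationary (default 0.5).
#' @param powerup_bigger_factor,powerup_bigger_duration_s "Bigger rockets":
#'   effective target-size multiplier and duration (defaults 1.5, 15 s).
#' @param powerup_freeze_duration_s "Target freeze": seconds during which the
#'   target speed is 0 (default 5 s).
#' @param powerup_rapid_factor,powerup_rapid_duration_s "Rapid fire":
#'   multiplier on the minimum inter-launch interval and duration
#'   (defaults 0.5, 10 s).
#' @param powerup_triple_count,powerup_triple_duration_s "Triple rockets":
#'   rockets per launch and duration (defaults 3, 10 s).
#' @param rng_seed Default seed used by [run_session()] when none is given.
#'
#' @return An object of class `game_config` (a validated named list).
#' @seealso [difficulty_params()], [compute_target_score()], [run_session()]
#' @examples
#' cfg <- game_config()
#' difficulty_params(2, cfg)
#' @export
game_config <- function(session_cap_s = 1800,
                        up_threshold = 0.60,
                        down_threshold = 0.30,
                        n_levels = 5,
                        speed_step = 0.25,
                        size_step = 0.10,
                        target_score_factor = 0.05,
                        boss_hits_required = 7,
                        boss_chain_window_s = 3,
                        base_target_speed = 1.0,
                        base_target_size = 1.0,
                        eval_window = 20,
                        eval_window_span_s = 60,
                        eval_min_attempts = 5,
                        boss_size_factor = 3.0,
                        boss_speed_factor = 1.0,
                        allow_boss_repeat = TRUE,
                        powerup_spawn_per_min = 1.0,
                        powerup_size_factor = 0.5,
                        powerup_bigger_factor = 1.5,
                        powerup_bigger_duration_s = 15,
                        powerup_freeze_duration_s = 5,
                        powerup_rapid_factor = 0.5,
                        powerup_rapid_duration_s = 10,
                        powerup_triple_count = 3,
                        powerup_triple_duration_s = 10,
                        rng_seed = 1L) {
  cfg <- list(
    session_cap_s = session_cap_s,
    up_threshold = up_threshold,
    down_threshold = down_threshold,
    n_levels = n_levels,
    speed_step = speed_step,
    size_step = size_step,
    target_score_factor = target_score_factor,
    boss_hits_required = boss_hits_required,
    boss_chain_window_s = boss_chain_window_s,
    base_target_speed = base_target_speed,
    base_target_size = base_target_size,
    eval_window = eval_window,
    eval_window_span_s = eval_window_span_s,
    eval_min_attempts = eval_min_attempts,
    boss_size_factor = boss_size_factor,
    boss_speed_factor = boss_speed_factor,
    allow_boss_repeat = isTRUE(allow_boss_repeat),
    powerup_spawn_per_min = powerup_spawn_per_min,
    powerup_size_factor = powerup_size_factor,
    powerup_bigger_factor = powerup_bigger_factor,
    powerup_bigger_duration_s = powerup_bigger_duration_s,
    powerup_freeze_duration_s = powerup_freeze_duration_s,
    powerup_rapid_factor = powerup_rapid_factor,
    powerup_rapid_duration_s = powerup_rapid_duration_s,
    powerup_triple_count = powerup_triple_count,
    powerup_triple_duration_s = powerup_triple_duration_s,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "game_config"
  validate_game_config(cfg)
  cfg
}

validate_game_config <- function(cfg) {
  check_scalar(cfg$session_cap_s, "session_cap_s", lo = 1e-9)
  check_scalar(cfg$up_threshold, "up_threshold", lo = 0, hi = 1)
  check_scalar(cfg$down_threshold, "down_threshold", lo = 0, hi = 1)
  if (!(cfg$down_threshold < cfg$up_threshold) ||
      cfg$down_threshold <= 0 || cfg$up_threshold >= 1) {
    stop_domain("thresholds must satisfy 0 < down_threshold < up_threshold < 1")
  }
  check_scalar(cfg$n_levels, "n_levels", lo = 1, integer = TRUE)
  for (f in c("speed_step", "size_step", "target_score_factor")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop_domain("'%s' must lie in (0, 1)", f)
    }
  }
  check_scalar(cfg$boss_hits_required, "boss_hits_required", lo = 1,
               integer = TRUE)
  check_scalar(cfg$boss_chain_window_s, "boss_chain_window_s", lo = 1e-9)
  check_scalar(cfg$base_target_speed, "base_target_speed", lo = 0)
  check_scalar(cfg$base_target_size, "base_target_size", lo = 1e-12)
  check_scalar(cfg$eval_window, "eval_window", lo = 1, integer = TRUE)
  check_scalar(cfg$eval_window_span_s, "eval_window_span_s", lo = 1e-9)
  check_scalar(cfg$eval_min_attempts, "eval_min_attempts", lo = 1,
               integer = TRUE)
  check_scalar(cfg$powerup_spawn_per_min, "powerup_spawn_per_min", lo = 0)
  invisible(cfg)
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat(sprintf("  session cap: %g s | levels: %d (start at 1)\n",
              x$session_cap_s, x$n_levels))
  cat(sprintf("  controller: up > %.0f%%, down < %.0f%%, window %d launches / %g s (min %d)\n",
              100 * x$up_threshold, 100 * x$down_threshold,
              x$eval_window, x$eval_window_span_s, x$eval_min_attempts))
  cat(sprintf("  per level: speed x%.2f, size x%.2f\n",
              1 + x$speed_step, 1 - x$size_step))
  cat(sprintf("  target score: high score + %.0f%% | boss: %d hits within %g s\n",
              100 * x$target_score_factor, x$boss_hits_required,
              x$boss_chain_window_s))
  invisible(x)
}

#' Power-up catalog
#'
#' The four power-up effects of the game and their configured magnitudes and
#' durations: bigger rockets (larger effective target size), target freeze
#' (target speed zero), rapid fire (shorter minimum inter-launch interval)
#' and triple rockets (several rockets per launch).
#'
#' @param config A [game_config()].
#' @return A data.frame with columns `effect`, `magnitude`, `duration_s`.
#' @export
powerup_catalog <- function(config = game_config()) {
  data.frame(
    effect = c("bigger_rockets", "target_freeze", "rapid_fire",
               "triple_rockets"),
    magnitude = c(config$powerup_bigger_factor, 0,
                  config$powerup_rapid_factor, config$powerup_triple_count),
    duration_s = c(config$powerup_bigger_duration_s,
                   config$powerup_freeze_duration_s,
                   config$powerup_rapid_duration_s,
                   config$powerup_triple_duration_s),
    stringsAsFactors = FALSE
  )
}

#' Target speed and size at a difficulty level
#'
#' Level 1 uses the base speed and size; each level multiplies the target
#' speed by `1 + speed_step` (default +25%) and the target size by
#' `1 - size_step` (default -10%), so higher levels demand faster tracking
#' and finer aim.
#'
#' @param level Integer difficulty level in `1..n_levels`.
#' @param config A [game_config()].
#' @return Named list with `target_speed` and `target_size`.
#' @examples
#' difficulty_params(2, game_config())  # speed 1.25, size 0.90
#' @export
difficulty_params <- function(level, config = game_config()) {
  check_scalar(level, "level", integer = TRUE)
  if (level < 1 || level > config$n_levels) {
    stop_domain("level must be in 1..%d, got %s", config$n_levels, level)
  }
  list(
    target_speed = config$base_target_speed * (1 + config$speed_step)^(level - 1),
    target_size = config$base_target_size * (1 - config$size_step)^(level - 1)
  )
}

#' Target score from the running high score
#'
#' The motivator rule: the target score sits `target_score_factor` (default
#' 5%) above the current high score, rounded half up, with a strict minimum
#' increment of one point so the target is always strictly above the high
#' score yet remains beatable.
#'
#' @param high_score Non-negative integer high score.
#' @param config A [game_config()].
#' @return Integer target score, always `> high_score`.
#' @examples
#' compute_target_score(100)  # 105
#' compute_target_score(0)    # 1
#' @export
compute_target_score <- function(high_score, config = game_config()) {
  check_scalar(high_score, "high_score", lo = 0, integer = TRUE)
  as.integer(max(high_score + 1,
                 round_half_up(high_score * (1 + config$target_score_factor))))
}
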