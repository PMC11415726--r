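# Headless game engine: score / boss / difficulty state machines and the
# session loop. All stochastic choices are driven by R's RNG, which
# run_session() seeds locally, so a (seed, config, policy) triple fully
# determines the event stream.

#' Score, boss and difficulty state constructors
#'
#' `score_state()` tracks the session score, the perpetual high score and the
#' derived target score (always strictly above the high score).
#' `boss_state()` tracks the chained boss battle. `difficulty_state()` holds
#' the current level, the level's target speed/size and the controller's
#' rolling window of recent robot-launch outcomes.
#'
#' @param high_score Starting high score for the session.
#' @param level Starting difficulty level (sessions start at level 1).
#' @param config A [game_config()].
#' @return A `score_state`, `boss_state` or `difficulty_state` list.
#' @export
score_state <- function(high_score = 0, config = game_config()) {
  check_scalar(high_score, "high_score", lo = 0, integer = TRUE)
  structure(
    list(session_score = 0L,
         high_score = as.integer(high_score),
         target_score = compute_target_score(high_score, config)),
    class = "score_state"
  )
}

#' @rdname score_state
#' @export
boss_state <- function(config = game_config()) {
  structure(
    list(active = FALSE, progress = 0L, last_hit_time = NA_real_,
         completed = FALSE, completions = 0L),
    class = "boss_state"
  )
}

#' @rdname score_state
#' @export
difficulty_state <- function(level = 1, config = game_config()) {
  dp <- difficulty_params(level, config)
  structure(
    list(level = as.integer(level),
         target_speed = dp$target_speed,
         target_size = dp$target_size,
         window_time = numeric(0),
         window_hit = logical(0)),
    class = "difficulty_state"
  )
}

#' Evaluate the adaptive-difficulty controller
#'
#' Computes the success rate over the rolling window (the most recent
#' `eval_window` robot launches no older than `eval_window_span_s` seconds)
#' and steps the level up when the rate exceeds `up_threshold`, down when it
#' falls below `down_threshold`, clamped to `1..n_levels`. No evaluation
#' happens until `eval_min_attempts` launches have accumulated. On a level
#' change the target speed/size are recomputed and the window is cleared, so
#' consecutive level changes are separated by at least `eval_min_attempts`
#' new launches.
#'
#' @param state A [difficulty_state()] whose window holds recent
#'   robot-launch outcomes.
#' @param config A [game_config()].
#' @param now Current session time in seconds used for the window age limit;
#'   defaults to the newest launch time in the window.
#' @return The updated `difficulty_state`.
#' @export
update_difficulty <- function(state, config = game_config(), now = NULL) {
  stopifnot(inherits(state, "difficulty_state"))
  n <- length(state$window_time)
  if (n == 0) {
    return(state)
  }
  if (is.null(now)) {
    now <- state$window_time[n]
  }
  keep <- state$window_time >= now - config$eval_window_span_s
  t <- state$window_time[keep]
  h <- state$window_hit[keep]
  if (length(t) > config$eval_window) {
    idx <- seq.int(length(t) - config$eval_window + 1L, length(t))
    t <- t[idx]
    h <- h[idx]
  }
  state$window_time <- t
  state$window_hit <- h
  if (length(h) < config$eval_min_attempts) {
    return(state)
  }
  rate <- mean(h)
  new_level <- state$level
  if (rate > config$up_threshold) {
    new_level <- min(state$level + 1L, config$n_levels)
  } else if (rate < config$down_threshold) {
    new_level <- max(state$level - 1L, 1L)
  }
  if (new_level != state$level) {
    dp <- difficulty_params(new_level, config)
    state$level <- as.integer(new_level)
    state$target_speed <- dp$target_speed
    state$target_size <- dp$target_size
    state$window_time <- numeric(0)
    state$window_hit <- logical(0)
  }
  state
}

#' Advance the boss battle by one hit
#'
#' A hit within `boss_chain_window_s` seconds of the previous hit extends the
#' chain; a longer gap restarts the chain at 1. The boss completes when the
#' chain reaches `boss_hits_required`.
#'
#' @param boss An active [boss_state()].
#' @param hit_time Session time of the hit in seconds.
#' @param config A [game_config()].
#' @return The updated `boss_state` (with `completed = TRUE` on the final
#'   chained hit).
#' @export
boss_update <- function(boss, hit_time, config = game_config()) {
  stopifnot(inherits(boss, "boss_state"))
  if (!boss$active) {
    stop_domain("boss_update() called while the boss battle is inactive")
  }
  check_scalar(hit_time, "hit_time", lo = 0)
  if (!is.na(boss$last_hit_time) && hit_time < boss$last_hit_time) {
    stop_domain("boss hit time %g precedes previous hit at %g",
                hit_time, boss$last_hit_time)
  }
  if (is.na(boss$last_hit_time) ||
      hit_time - boss$last_hit_time <= config$boss_chain_window_s) {
    boss$progress <- boss$progress + 1L
  } else {
    boss$progress <- 1L
  }
  boss$last_hit_time <- hit_time
  boss$completed <- boss$progress >= config$boss_hits_required
  boss
}

#' Apply one attempt outcome to the score and boss states
#'
#' Robot hits add one point; misses change nothing; power-up hits activate
#' their effect but score no points; boss hits add one point and advance the
#' boss chain. The boss battle activates exactly when the session score first
#' reaches the target score, and on completion the high score and target
#' score are refreshed immediately (the session continues; whether the boss
#' can be unlocked again is governed by `allow_boss_repeat`).
#'
#' @param score A [score_state()].
#' @param boss A [boss_state()].
#' @param event List with at least `timestamp_s` and `outcome` (one of
#'   `"hit_robot"`, `"miss"`, `"hit_powerup"`, `"hit_boss"`); a power-up hit
#'   may carry `effect`.
#' @param config A [game_config()].
#' @return List with updated `score`, `boss`, and `activated` (the power-up
#'   effect name, or `NULL`).
#' @export
register_attempt <- function(score, boss, event, config = game_config()) {
  stopifnot(inherits(score, "score_state"), inherits(boss, "boss_state"))
  outcome <- match.arg(event$outcome,
                       c("hit_robot", "miss", "hit_powerup", "hit_boss"))
  activated <- NULL
  if (outcome == "hit_robot") {
    score$session_score <- score$session_score + 1L
  } else if (outcome == "hit_powerup") {
    activated <- event$effect %||% NA_character_
  } else if (outcome == "hit_boss") {
    boss <- boss_update(boss, event$timestamp_s, config)
    score$session_score <- score$session_score + 1L
    if (boss$completed) {
      score$high_score <- max(score$high_score, score$session_score)
      score$target_score <- compute_target_score(score$high_score, config)
      boss$active <- FALSE
      boss$progress <- 0L
      boss$last_hit_time <- NA_real_
      boss$completed <- FALSE
      boss$completions <- boss$completions + 1L
    }
  }
  if (!boss$active && score$session_score >= score$target_score &&
      (boss$completions == 0L || config$allow_boss_repeat)) {
    boss$active <- TRUE
    boss$progress <- 0L
    boss$last_hit_time <- NA_real_
    boss$completed <- FALSE
  }
  list(score = score, boss = boss, activated = activated)
}

#' Run one headless game session
#'
#' Plays a full session of the rocket game against a player policy and
#' returns the per-attempt event log plus session metadata. The loop draws
#' attempt timing and outcomes from the policy, spawns power-up orbs as a
#' Poisson process, runs the adaptive-difficulty controller after every
#' robot launch, and ends when the session cap is reached (the game exits
#' automatically) or when the policy stops firing. The same
#' (policy, config, seed, high_score) always reproduces the same event
#' stream.
#'
#' @param policy A player policy, e.g. from [player_policy()]: a list with
#'   `next_attempt(ctx)` returning `NULL` or `list(dt, hand)` and
#'   `hit_prob(ctx, aim, speed, size)` returning a probability. `ctx` carries
#'   the session time, level, active effects, boss state and practice hours.
#' @param config A [game_config()].
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @param high_score High score carried into the session (perpetual tracker).
#' @param practice_hours Cumulative practice hours before this session,
#'   passed to the policy so motor learning can continue within the session.
#' @return A `session_record`: list with `events` (data.frame
#'   `timestamp_s, hand, outcome, level, powerups, score_after`), `seed`,
#'   `config_hash`, `duration_s`, `final_score`, `high_score_start`,
#'   `high_score_end`, `boss_completions`, `practice_hours_start`.
#' @examples
#' rec <- run_session(policy_never_fires(), game_config(), seed = 1)
#' nrow(rec$events)  # 0 attempts
#' @export
run_session <- function(policy, config = game_config(),
                        seed = config$rng_seed, high_score = 0,
                        practice_hours = 0) {
  stopifnot(is.list(policy), is.function(policy$next_attempt),
            is.function(policy$hit_prob))
  withr::local_seed(as.integer(seed))

  cap <- config$session_cap_s
  score <- score_state(high_score, config)
  boss <- boss_state(config)
  diff <- difficulty_state(1, config)
  catalog <- powerup_catalog(config)

  # Power-up spawn times: homogeneous Poisson process over the session.
  n_spawn <- stats::rpois(1, config$powerup_spawn_per_min * cap / 60)
  spawn_times <- sort(stats::runif(n_spawn, 0, cap))
  spawn_types <- sample(catalog$effect, size = n_spawn, replace = TRUE)
  spawn_next <- 1L
  avail_types <- character(0)

  # Active effect expiry times.
  expiry <- c(bigger_rockets = -Inf, target_freeze = -Inf,
              rapid_fire = -Inf, triple_rockets = -Inf)

  # Growable event columns.
  cap_n <- 4096L
  ev_t <- numeric(cap_n); ev_hand <- character(cap_n)
  ev_out <- character(cap_n); ev_lvl <- integer(cap_n)
  ev_pow <- character(cap_n); ev_score <- integer(cap_n)
  n_ev <- 0L

  t <- 0
  repeat {
    effects <- names(expiry)[expiry >= t]
    ctx <- list(
      t = t, cap = cap, level = diff$level,
      target_speed = diff$target_speed, target_size = diff$target_size,
      effects = effects, boss_active = boss$active,
      powerup_available = length(avail_types) +
        sum(spawn_times[seq_len(n_spawn) >= spawn_next] <= t),
      practice_hours = practice_hours + t / 3600,
      config = config
    )
    att <- policy$next_attempt(ctx)
    if (is.null(att)) break
    t_new <- t + att$dt
    if (t_new > cap) break
    t <- round(t_new, 3)

    # Reveal power-ups spawned before this launch.
    while (spawn_next <= n_spawn && spawn_times[spawn_next] <= t) {
      avail_types <- c(avail_types, spawn_types[spawn_next])
      spawn_next <- spawn_next + 1L
    }
    effects <- names(expiry)[expiry >= t]

    # Aim: the boss monopolises attention while active; otherwise an
    # available power-up orb may be targeted, else a robot.
    if (boss$active) {
      aim <- "boss"
    } else if (length(avail_types) > 0 &&
               stats::runif(1) < (policy$powerup_aim_prob %||% 0.8)) {
      aim <- "powerup"
    } else {
      aim <- "robot"
    }

    frozen <- "target_freeze" %in% effects
    bigger <- "bigger_rockets" %in% effects
    size_mult <- if (bigger) config$powerup_bigger_factor else 1
    if (aim == "robot") {
      speed <- if (frozen) 0 else diff$target_speed
      size <- diff$target_size * size_mult
    } else if (aim == "powerup") {
      speed <- 0
      size <- diff$target_size * config$powerup_size_factor * size_mult
    } else {
      speed <- if (frozen) 0 else diff$target_speed * config$boss_speed_factor
      size <- diff$target_size * config$boss_size_factor * size_mult
    }

    ctx$t <- t
    ctx$effects <- effects
    p <- policy$hit_prob(ctx, aim, speed, size)
    if ("triple_rockets" %in% effects) {
      p <- 1 - (1 - p)^config$powerup_triple_count
    }
    hit <- stats::runif(1) < p

    if (aim == "robot") {
      outcome <- if (hit) "hit_robot" else "miss"
    } else if (aim == "powerup") {
      outcome <- if (hit) "hit_powerup" else "miss"
    } else {
      outcome <- if (hit) "hit_boss" else "miss"
    }

    event <- list(timestamp_s = t, outcome = outcome)
    if (outcome == "hit_powerup") {
      pick <- sample.int(length(avail_types), 1)
      event$effect <- avail_types[pick]
      avail_types <- avail_types[-pick]
    }
    upd <- register_attempt(score, boss, event, config)
    score <- upd$score
    boss <- upd$boss
    if (!is.null(upd$activated) && !is.na(upd$activated)) {
      dur <- catalog$duration_s[match(upd$activated, catalog$effect)]
      expiry[[upd$activated]] <- t + dur
    }

    # Difficulty controller sees robot-directed launches only.
    if (aim == "robot") {
      diff$window_time <- c(diff$window_time, t)
      diff$window_hit <- c(diff$window_hit, hit)
      diff <- update_difficulty(diff, config, now = t)
    }

    n_ev <- n_ev + 1L
    if (n_ev > cap_n) {
      cap_n <- cap_n * 2L
      length(ev_t) <- cap_n; length(ev_hand) <- cap_n
      length(ev_out) <- cap_n; length(ev_lvl) <- cap_n
      length(ev_pow) <- cap_n; length(ev_score) <- cap_n
    }
    ev_t[n_ev] <- t
    ev_hand[n_ev] <- att$hand %||% "dominant"
    ev_out[n_ev] <- outcome
    ev_lvl[n_ev] <- diff$level
    ev_pow[n_ev] <- paste(effects, collapse = "|")
    ev_score[n_ev] <- score$session_score
  }

  events <- data.frame(
    timestamp_s = ev_t[seq_len(n_ev)],
    hand = ev_hand[seq_len(n_ev)],
    outcome = ev_out[seq_len(n_ev)],
    level = ev_lvl[seq_len(n_ev)],
    powerups = ev_pow[seq_len(n_ev)],
    score_after = ev_score[seq_len(n_ev)],
    stringsAsFactors = FALSE
  )
  high_end <- max(score$high_score, score$session_score)
  structure(
    list(events = events,
         seed = as.integer(seed),
         config = config,
         config_hash = config_hash(config),
         duration_s = cap,
         final_score = score$session_score,
         high_score_start = as.integer(high_score),
         high_score_end = as.integer(high_end),
         boss_completions = boss$completions,
         practice_hours_start = practice_hours,
         phase = NA_character_,
         session_id = NA_character_,
         date = NA_character_),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  m <- session_metrics(x)
  cat("<session_record>\n")
  cat(sprintf("  %d attempts in %.1f min | score %d (high %d -> %d)\n",
              m$attempts, x$duration_s / 60, x$final_score,
              x$high_score_start, x$high_score_end))
  cat(sprintf("  accuracy %.3f | %.1f shots/min | %d boss completion(s)\n",
              m$accuracy, m$shots_per_minute, x$boss_completions))
  invisible(x)
}

#' Task-performance metrics of a session
#'
#' Summarises one session's event log into the task-performance measures of
#' the study: game score (robot + boss hits), number of attempts (every
#' rocket launched), task accuracy (scoring hits over all launches; power-up
#' hits count in the denominator only), and firing rate in shots per minute.
#'
#' @param record A `session_record` from [run_session()].
#' @return One-row data.frame with `score`, `attempts`, `accuracy`,
#'   `shots_per_minute`, `boss_completions`, `duration_min`.
#' @export
session_metrics <- function(record) {
  stopifnot(inherits(record, "session_record"))
  ev <- record$events
  attempts <- nrow(ev)
  hits <- sum(ev$outcome %in% c("hit_robot", "hit_boss"))
  data.frame(
    score = record$final_score,
    attempts = attempts,
    accuracy = if (attempts > 0) hits / attempts else NA_real_,
    shots_per_minute = attempts / (record$duration_s / 60),
    boss_completions = record$boss_completions,
    duration_min = record$duration_s / 60
  )
}

#' A policy that never fires
#'
#' Minimal player policy whose `next_attempt()` immediately ends the session;
#' useful as a degenerate baseline and for tests.
#'
#' @return A policy usable with [run_session()].
#' @export
policy_never_fires <- function() {
  list(
    next_attempt = function(ctx) NULL,
    hit_prob = function(ctx, aim, speed, size) 0,
    powerup_aim_prob = 0
  )
}
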