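# Virtual player: parametric stand-in for the child. Hit probabilities as a
# function of task demand and skill, two-stage (fast-then-slow) motor
# learning, attempt timing, and synthetic per-hand controller accelerometry.

#' Virtual-player parameters
#'
#' Describes the simulated player: starting skill, two-stage motor-learning
#' dynamics (a fast early phase followed by a slow incremental phase), firing
#' rate and its growth with skill, dominant/nondominant movement asymmetry,
#' and the accelerometry burst model.
#'
#' The real player's motor behaviour is unobservable; these are free
#' parameters. The defaults are a documented calibration chosen so that a
#' novice playing 30-minute sessions produces baseline task accuracy in the
#' mid-60% range and, after roughly 14 practice hours, accuracy and firing
#' rate in the high-80% / mid-30-per-minute range — the operating regime of
#' the home study this package models. See the methods vignette.
#'
#' @param skill Starting skill `s0` (unitless, >= 0; default 1).
#' @param skill_gain_fast,skill_gain_slow Asymptotic skill gains `A` and `B`
#'   of the fast and slow learning stages (defaults 0.45, 0.35).
#' @param learn_rate_fast,learn_rate_slow Learning rates in 1/hour (defaults
#'   1.2 and 0.15; fast must exceed slow).
#' @param fast_phase_hours Duration of the fast learning stage in practice
#'   hours (default 2).
#' @param fire_rate_base,fire_rate_gain Launches per minute as
#'   `fire_rate_base + fire_rate_gain * skill` (defaults 12.5, 12.5: 25/min
#'   at skill 1).
#' @param min_fire_interval_s Minimum time between launches in seconds
#'   (default 0.8; rapid-fire halves it).
#' @param hand_asymmetry Fraction in (0, 1] scaling nondominant movement
#'   amplitude (default 0.45).
#' @param fatigue_rate Linear within-session decrement of firing rate in
#'   1/hour (default 0 = off).
#' @param dominant_hold_prob Probability the dominant hand holds the rocket
#'   on a given attempt (default 0.5; the task is bimanual either way).
#' @param skill_scale,demand_scale Coefficients `a` and `b` of the hit model
#'   `p = logistic(a * skill - b * speed / size)` (defaults 2, 0.4).
#' @param boss_fire_factor Multiplier on the inter-launch interval during the
#'   boss battle (default 0.5: rapid succession is the boss's demand).
#' @param powerup_aim_prob Probability of aiming at an available power-up orb
#'   instead of a robot (default 0.8).
#' @param burst_amp_g Peak acceleration of a dominant-hand movement burst in
#'   g (default 1.0).
#' @param burst_freq_hz,burst_tau_s,burst_duration_s Burst oscillation
#'   frequency, damping time constant and duration (defaults 1.5 Hz, 0.25 s,
#'   0.6 s; the frequency sits inside the activity-counts band).
#' @param noise_sd_g Sensor white-noise standard deviation per axis in g
#'   (default 0.02).
#' @param rng_seed Default seed for accelerometry generation.
#' @return An object of class `player_params`.
#' @seealso [hit_probability()], [learning_update()], [player_policy()],
#'   [simulate_study()]
#' @export
player_params <- function(skill = 1,
                          skill_gain_fast = 0.45,
                          skill_gain_slow = 0.35,
                          learn_rate_fast = 1.2,
                          learn_rate_slow = 0.15,
                          fast_phase_hours = 2,
                          fire_rate_base = 12.5,
                          fire_rate_gain = 12.5,
                          min_fire_interval_s = 0.8,
                          hand_asymmetry = 0.45,
                          fatigue_rate = 0,
                          dominant_hold_prob = 0.5,
                          skill_scale = 2,
                          demand_scale = 0.4,
                          boss_fire_factor = 0.5,
                          powerup_aim_prob = 0.8,
                          burst_amp_g = 1.0,
                          burst_freq_hz = 1.5,
                          burst_tau_s = 0.25,
                          burst_duration_s = 0.6,
                          noise_sd_g = 0.02,
                          rng_seed = 1L) {
  p <- list(skill = skill, skill_gain_fast = skill_gain_fast,
            skill_gain_slow = skill_gain_slow,
            learn_rate_fast = learn_rate_fast,
            learn_rate_slow = learn_rate_slow,
            fast_phase_hours = fast_phase_hours,
            fire_rate_base = fire_rate_base,
            fire_rate_gain = fire_rate_gain,
            min_fire_interval_s = min_fire_interval_s,
            hand_asymmetry = hand_asymmetry,
            fatigue_rate = fatigue_rate,
            dominant_hold_prob = dominant_hold_prob,
            skill_scale = skill_scale, demand_scale = demand_scale,
            boss_fire_factor = boss_fire_factor,
            powerup_aim_prob = powerup_aim_prob,
            burst_amp_g = burst_amp_g, burst_freq_hz = burst_freq_hz,
            burst_tau_s = burst_tau_s, burst_duration_s = burst_duration_s,
            noise_sd_g = noise_sd_g, rng_seed = as.integer(rng_seed))
  class(p) <- "player_params"
  validate_player_params(p)
  p
}

validate_player_params <- function(p) {
  check_scalar(p$skill, "skill", lo = 0)
  check_scalar(p$skill_gain_fast, "skill_gain_fast", lo = 0)
  check_scalar(p$skill_gain_slow, "skill_gain_slow", lo = 0)
  check_scalar(p$learn_rate_fast, "learn_rate_fast", lo = 0)
  check_scalar(p$learn_rate_slow, "learn_rate_slow", lo = 0)
  if (!(p$learn_rate_fast > p$learn_rate_slow)) {
    stop_domain("learn_rate_fast must exceed learn_rate_slow")
  }
  check_scalar(p$fast_phase_hours, "fast_phase_hours", lo = 0)
  check_scalar(p$fire_rate_base, "fire_rate_base", lo = 1e-9)
  check_scalar(p$min_fire_interval_s, "min_fire_interval_s", lo = 0)
  if (p$hand_asymmetry <= 0 || p$hand_asymmetry > 1) {
    stop_domain("hand_asymmetry must lie in (0, 1]")
  }
  check_scalar(p$dominant_hold_prob, "dominant_hold_prob", lo = 0, hi = 1)
  invisible(p)
}

#' Hit probability of one rocket launch
#'
#' Logistic link between player skill and the task demand ratio
#' `speed / size`: `p = logistic(skill_scale * skill -
#' demand_scale * speed / size)`. The probability is strictly decreasing in
#' target speed, strictly increasing in target size (for moving targets) and
#' strictly increasing in skill. Active power-up effects may be passed:
#' `"target_freeze"` sets the speed to 0 and `"bigger_rockets"` scales the
#' effective size by 1.5.
#'
#' @param params A [player_params()].
#' @param speed Target speed (>= 0).
#' @param size Target size (> 0).
#' @param powerups Character vector of active effect names.
#' @return Hit probability in `[0, 1]`.
#' @examples
#' p <- player_params()
#' hit_probability(p, speed = 0, size = 1)   # frozen target: near-certain
#' hit_probability(p, speed = 2, size = 0.9)
#' @export
hit_probability <- function(params, speed, size, powerups = character()) {
  stopifnot(inherits(params, "player_params"))
  if (any(size <= 0)) {
    stop_domain("target size must be positive")
  }
  if (any(speed < 0)) {
    stop_domain("target speed must be non-negative")
  }
  if ("target_freeze" %in% powerups) speed <- 0
  if ("bigger_rockets" %in% powerups) size <- size * 1.5
  clamp(stats::plogis(params$skill_scale * params$skill -
                        params$demand_scale * speed / size), 0, 1)
}

#' Skill after a given amount of practice
#'
#' Two-stage motor-learning curve: a fast exponential stage over the first
#' `fast_phase_hours` of practice followed by a slow exponential stage, i.e.
#' `skill(t) = s0 + A * (1 - exp(-rf * min(t, tf))) +
#' B * (1 - exp(-rs * max(0, t - tf)))`. The curve is nondecreasing and
#' concave within each stage, reproducing the sharp-early / incremental-late
#' pattern of motor learning.
#'
#' @param params A [player_params()].
#' @param cumulative_practice Practice time in hours (vectorised, >= 0).
#' @return Skill value(s).
#' @export
learning_update <- function(params, cumulative_practice) {
  stopifnot(inherits(params, "player_params"))
  if (any(!is.finite(cumulative_practice)) || any(cumulative_practice < 0)) {
    stop_domain("cumulative_practice must be finite and non-negative")
  }
  t <- cumulative_practice
  tf <- params$fast_phase_hours
  params$skill +
    params$skill_gain_fast *
      (1 - exp(-params$learn_rate_fast * pmin(t, tf))) +
    params$skill_gain_slow *
      (1 - exp(-params$learn_rate_slow * pmax(0, t - tf)))
}

#' Asymptotic accuracy implied by the learning model
#'
#' The hit probability a fully learned player attains against a plain robot
#' target at the top difficulty level. The skill limit is the exact limit of
#' the two-stage curve, `s0 + A (1 - exp(-rf * tf)) + B` (the fast stage
#' stops accruing at `tf`). Used as the reference value in learning-curve
#' parameter-recovery checks.
#'
#' @param params A [player_params()].
#' @param config A [game_config()].
#' @return Probability in `[0, 1]`.
#' @export
learning_asymptote <- function(params, config = game_config()) {
  dp <- difficulty_params(config$n_levels, config)
  s_inf <- params$skill +
    params$skill_gain_fast *
      (1 - exp(-params$learn_rate_fast * params$fast_phase_hours)) +
    params$skill_gain_slow
  p_inf <- player_params_with_skill(params, s_inf)
  hit_probability(p_inf, dp$target_speed, dp$target_size)
}

player_params_with_skill <- function(params, skill) {
  params$skill <- skill
  params
}

#' Player policy for the session loop
#'
#' Wraps a [player_params()] into the policy interface consumed by
#' [run_session()]: attempt timing (minimum interval plus an exponential
#' component whose rate grows with skill; faster during the boss battle,
#' shorter minimum under rapid-fire, optionally slowed by fatigue) and hit
#' probabilities via [hit_probability()] at the skill implied by cumulative
#' practice.
#'
#' @param params A [player_params()].
#' @return A policy list with `next_attempt`, `hit_prob`, and
#'   `powerup_aim_prob`.
#' @export
player_policy <- function(params) {
  stopifnot(inherits(params, "player_params"))
  force(params)
  list(
    next_attempt = function(ctx) {
      skill <- learning_update(params, ctx$practice_hours)
      rate <- params$fire_rate_base + params$fire_rate_gain * skill
      if (params$fatigue_rate > 0) {
        rate <- rate * max(0.2, 1 - params$fatigue_rate * ctx$t / 3600)
      }
      min_int <- params$min_fire_interval_s
      if ("rapid_fire" %in% ctx$effects) {
        min_int <- min_int * ctx$config$powerup_rapid_factor
      }
      mean_exp <- max(0.05, 60 / rate - params$min_fire_interval_s)
      dt <- min_int + stats::rexp(1, rate = 1 / mean_exp)
      if (ctx$boss_active) {
        dt <- dt * params$boss_fire_factor
      }
      hand <- if (stats::runif(1) < params$dominant_hold_prob) {
        "dominant"
      } else {
        "nondominant"
      }
      list(dt = dt, hand = hand)
    },
    hit_prob = function(ctx, aim, speed, size) {
      skill <- learning_update(params, ctx$practice_hours)
      hit_probability(player_params_with_skill(params, skill), speed, size)
    },
    powerup_aim_prob = params$powerup_aim_prob
  )
}

#' Study protocol
#'
#' The single-case study design: 3 weekly baseline sessions, an intervention
#' block prescribed as two 30-minute sessions per day toward a 14-hour dose,
#' an adherence pattern of full / half / skipped days, and one post session a
#' week after the intervention ends.
#'
#' @param n_baseline_sessions Number of baseline sessions (default 3).
#' @param baseline_spacing_days Days between baseline sessions (default 7).
#' @param prescribed_sessions_per_day Sessions prescribed on a full day
#'   (default 2).
#' @param session_minutes Minutes per session (default 30).
#' @param dose_target_hours Treatment dose target in hours (default 14).
#' @param adherence_pattern Character vector over `"F"` (full), `"H"` (half),
#'   `"N"` (none), one element per calendar day of the intervention block.
#'   The default, [default_adherence_pattern()], is a synthetic 22-day
#'   calendar with 11 full, 5 half and 6 skipped days.
#' @param post_delay_days Days between the last intervention day and the post
#'   session (default 7).
#' @param start_date Calendar date of intervention day 1 (default
#'   `"2024-04-01"`).
#' @param initial_high_score High score carried into the first baseline
#'   session; the perpetual high-score tracker is assumed primed by earlier
#'   familiarisation play (default 400).
#' @return An object of class `study_protocol`.
#' @export
study_protocol <- function(n_baseline_sessions = 3,
                           baseline_spacing_days = 7,
                           prescribed_sessions_per_day = 2,
                           session_minutes = 30,
                           dose_target_hours = 14,
                           adherence_pattern = default_adherence_pattern(),
                           post_delay_days = 7,
                           start_date = "2024-04-01",
                           initial_high_score = 400) {
  if (is.character(adherence_pattern) && length(adherence_pattern) == 1 &&
      nchar(adherence_pattern) > 1) {
    adherence_pattern <- strsplit(adherence_pattern, "")[[1]]
  }
  if (length(adherence_pattern) == 0 ||
      !all(adherence_pattern %in% c("F", "H", "N"))) {
    stop_domain("adherence_pattern must be a nonempty sequence over F/H/N")
  }
  p <- list(n_baseline_sessions = as.integer(n_baseline_sessions),
            baseline_spacing_days = as.integer(baseline_spacing_days),
            prescribed_sessions_per_day = as.integer(prescribed_sessions_per_day),
            session_minutes = session_minutes,
            dose_target_hours = dose_target_hours,
            adherence_pattern = adherence_pattern,
            post_delay_days = as.integer(post_delay_days),
            start_date = as.Date(start_date),
            initial_high_score = as.integer(initial_high_score))
  class(p) <- "study_protocol"
  check_scalar(p$n_baseline_sessions, "n_baseline_sessions", lo = 0,
               integer = TRUE)
  check_scalar(p$session_minutes, "session_minutes", lo = 1e-9)
  p
}

#' Synthetic 22-day adherence calendar
#'
#' A synthetic intervention calendar with 11 full days (two 30-minute
#' sessions), 5 half days (one session) and 6 skipped days over 22 calendar
#' days — skipped days clustered early and half days in the middle, matching
#' the reported adherence narrative of the home study this package models.
#'
#' @return Character vector of length 22 over `"F"`, `"H"`, `"N"`.
#' @export
default_adherence_pattern <- function() {
  c("F", "F", "N", "N", "F", "F", "N", "F", "F", "H", "F",
    "H", "F", "H", "N", "H", "F", "H", "N", "N", "F", "F")
}

#' Simulate a complete single-case study
#'
#' Runs the full study design against the virtual player: baseline sessions,
#' the intervention block following the adherence pattern (two sessions on
#' full days, one on half days, none on skipped days), and one post session.
#' Skill carries over between sessions through cumulative practice hours, and
#' the high score persists across the whole study. Each session can carry
#' per-hand 120 Hz accelerometry.
#'
#' @param protocol A [study_protocol()].
#' @param params A [player_params()].
#' @param config A [game_config()].
#' @param seed Integer master seed; per-session seeds are derived from it.
#' @param include_accel Generate per-hand accelerometry for every session
#'   (default FALSE; the event logs alone are much lighter and enough for
#'   task-performance analyses). Accelerometry for individual sessions can
#'   always be regenerated with [generate_accel()].
#' @return A `study_dataset`: list with `sessions` (list of session records,
#'   each tagged with `phase`, `session_id`, `date`, `start_time` and, if
#'   requested, `accel`), plus `protocol`, `params`, `config`, `seed`.
#' @examples
#' proto <- study_protocol(adherence_pattern = c("F", "N"),
#'                         n_baseline_sessions = 1)
#' cfg <- game_config(session_cap_s = 60)
#' ds <- simulate_study(proto, player_params(), cfg, seed = 1)
#' length(ds$sessions)  # 1 baseline + 2 intervention + 1 post
#' @export
simulate_study <- function(protocol = study_protocol(),
                           params = player_params(),
                           config = game_config(),
                           seed = 1L,
                           include_accel = FALSE) {
  stopifnot(inherits(protocol, "study_protocol"),
            inherits(params, "player_params"),
            inherits(config, "game_config"))
  plan <- list()
  day0 <- protocol$start_date
  if (protocol$n_baseline_sessions > 0) {
    for (i in seq_len(protocol$n_baseline_sessions)) {
      offset <- (protocol$n_baseline_sessions - i + 1) *
        protocol$baseline_spacing_days
      plan[[length(plan) + 1]] <- list(phase = "baseline",
                                       date = day0 - offset, slot = 1L)
    }
  }
  for (d in seq_along(protocol$adherence_pattern)) {
    cls <- protocol$adherence_pattern[[d]]
    n_today <- switch(cls,
                      F = protocol$prescribed_sessions_per_day,
                      H = 1L, N = 0L)
    if (n_today > 0) {
      for (s in seq_len(n_today)) {
        plan[[length(plan) + 1]] <- list(phase = "intervention",
                                         date = day0 + (d - 1), slot = s)
      }
    }
  }
  last_day <- day0 + length(protocol$adherence_pattern) - 1
  plan[[length(plan) + 1]] <- list(phase = "post",
                                   date = last_day + protocol$post_delay_days,
                                   slot = 1L)

  session_cfg <- config
  session_cfg$session_cap_s <- protocol$session_minutes * 60
  sessions <- vector("list", length(plan))
  high <- protocol$initial_high_score
  practice <- 0
  for (k in seq_along(plan)) {
    pk <- plan[[k]]
    s_seed <- derive_seed(seed, k)
    rec <- run_session(player_policy(params), session_cfg, seed = s_seed,
                       high_score = high, practice_hours = practice)
    rec$phase <- pk$phase
    rec$date <- as.character(pk$date)
    rec$start_time <- sprintf("%s %02d:00:00", pk$date,
                              if (pk$slot == 1L) 10L else 16L)
    rec$session_id <- sprintf("S%02d_%s_%s", k, pk$phase,
                              format(pk$date, "%Y%m%d"))
    if (include_accel) {
      rec$accel <- list(
        dominant = generate_accel(rec, params, "dominant",
                                  seed = derive_seed(s_seed, 1)),
        nondominant = generate_accel(rec, params, "nondominant",
                                     seed = derive_seed(s_seed, 2))
      )
    }
    sessions[[k]] <- rec
    high <- rec$high_score_end
    practice <- practice + protocol$session_minutes / 60
  }
  structure(list(sessions = sessions, protocol = protocol, params = params,
                 config = config, seed = as.integer(seed)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  phases <- vapply(x$sessions, `[[`, character(1), "phase")
  cat("<study_dataset>\n")
  cat(sprintf("  %d sessions: %d baseline, %d intervention, %d post\n",
              length(x$sessions), sum(phases == "baseline"),
              sum(phases == "intervention"), sum(phases == "post")))
  cat(sprintf("  seed %d | pattern %s\n", x$seed,
              paste(x$protocol$adherence_pattern, collapse = "")))
  invisible(x)
}

#' Per-session task-performance metrics of a study
#'
#' Flattens a simulated (or reconstructed) study into one row per session
#' with its phase, date, cumulative practice hours and the
#' [session_metrics()] columns.
#'
#' @param dataset A `study_dataset`.
#' @return data.frame with `session_index`, `session_id`, `date`, `phase`,
#'   `practice_hours`, `score`, `attempts`, `accuracy`, `shots_per_minute`,
#'   `boss_completions`, `duration_min`.
#' @export
study_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- lapply(seq_along(dataset$sessions), function(k) {
    s <- dataset$sessions[[k]]
    cbind(data.frame(session_index = k, session_id = s$session_id,
                     date = s$date, phase = s$phase,
                     practice_hours = s$practice_hours_start,
                     stringsAsFactors = FALSE),
          session_metrics(s))
  })
  do.call(rbind, rows)
}

#' Synthetic controller accelerometry for one session
#'
#' Generates a per-hand 3-axis acceleration series at 120 Hz spanning the
#' session: a constant gravity component plus white sensor noise, with a
#' damped-oscillation movement burst centred on every attempt. The task is
#' bimanual (one hand holds, the other touches), so both hands receive a
#' burst for every attempt; nondominant bursts are scaled by
#' `hand_asymmetry`. Burst directions are random unit vectors; the envelope
#' is deterministic, so the nondominant/dominant burst energy ratio equals
#' `hand_asymmetry` exactly up to sensor noise.
#'
#' @param session A `session_record` from [run_session()].
#' @param params A [player_params()].
#' @param hand `"dominant"` or `"nondominant"`.
#' @param sample_rate Sampling rate in Hz (default 120).
#' @param seed Integer seed (defaults to a value derived from the session
#'   seed and the hand).
#' @return An [accel_series()] with `round(duration_s * sample_rate)`
#'   samples.
#' @export
generate_accel <- function(session, params, hand, sample_rate = 120,
                           seed = NULL) {
  stopifnot(inherits(session, "session_record"),
            inherits(params, "player_params"))
  if (!hand %in% c("dominant", "nondominant")) {
    stop_domain("unknown hand label: %s", hand)
  }
  if (is.null(seed)) {
    seed <- derive_seed(session$seed, if (hand == "dominant") 1L else 2L)
  }
  withr::local_seed(as.integer(seed))

  n <- round(session$duration_s * sample_rate)
  gravity <- c(0, 0, 1)
  acc <- matrix(stats::rnorm(n * 3, sd = params$noise_sd_g), ncol = 3)
  acc <- sweep(acc, 2, gravity, `+`)

  amp <- params$burst_amp_g *
    if (hand == "nondominant") params$hand_asymmetry else 1
  ev_t <- session$events$timestamp_s
  if (length(ev_t) > 0) {
    burst_n <- max(1L, round(params$burst_duration_s * sample_rate))
    tau <- seq(0, by = 1 / sample_rate, length.out = burst_n)
    envelope <- amp * exp(-tau / params$burst_tau_s) *
      sin(2 * pi * params$burst_freq_hz * tau)
    for (t0 in ev_t) {
      i0 <- floor(t0 * sample_rate) + 1L
      idx <- i0:min(i0 + burst_n - 1L, n)
      if (length(idx) == 0 || idx[1] > n) next
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      seg <- envelope[seq_along(idx)]
      acc[idx, ] <- acc[idx, ] + outer(seg, dir)
    }
  }
  accel_series(acc, sample_rate = sample_rate, hand = hand,
               start_time = session$start_time %||% NA_character_)
}

#' Fit the two-stage learning curve to accuracy-by-session data
#'
#' Fits `logit(accuracy) = z0 + ka * (1 - exp(-rf * min(t, tf))) +
#' kb * (1 - exp(-rs * max(0, t - tf)))` over cumulative practice hours `t`
#' by nonlinear least squares, with the fast-phase duration `tf` treated as a
#' known design constant. The logit scale is used because, at a fixed
#' difficulty level, the hit model makes log-odds of success affine in
#' skill, so the skill curve's rates transfer to the accuracy curve.
#'
#' @param hours Cumulative practice hours per session.
#' @param accuracy Session accuracy in (0, 1).
#' @param fast_phase_hours Fast-phase duration `tf` in hours (default 2).
#' @return List with `learn_rate_fast`, `learn_rate_slow`, `asymptote`
#'   (accuracy as `t -> Inf`), the raw coefficients, and `fitted` values on
#'   the accuracy scale.
#' @export
fit_learning_curve <- function(hours, accuracy, fast_phase_hours = 2) {
  stopifnot(length(hours) == length(accuracy), length(hours) >= 5)
  if (any(accuracy <= 0 | accuracy >= 1)) {
    stop_domain("accuracy values must lie strictly inside (0, 1)")
  }
  z <- stats::qlogis(accuracy)
  t <- hours
  tf <- fast_phase_hours
  df <- data.frame(z = z, t = t)
  i_tf <- which.min(abs(t - tf))
  start <- list(z0 = z[which.min(t)],
                ka = max(z[i_tf] - z[which.min(t)], 0.1),
                kb = max(z[which.max(t)] - z[i_tf], 0.1),
                rf = 1, rs = 0.1)
  fit <- minpack.lm::nlsLM(
    z ~ z0 + ka * (1 - exp(-rf * pmin(t, tf))) +
      kb * (1 - exp(-rs * pmax(0, t - tf))),
    data = df, start = start,
    lower = c(z0 = -Inf, ka = 0, kb = 0, rf = 1e-6, rs = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- as.list(stats::coef(fit))
  list(learn_rate_fast = co$rf,
       learn_rate_slow = co$rs,
       asymptote = stats::plogis(co$z0 +
                                   co$ka * (1 - exp(-co$rf * tf)) + co$kb),
       coefficients = co,
       fitted = stats::plogis(stats::fitted(fit)))
}
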