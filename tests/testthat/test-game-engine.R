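cfg <- game_config()

test_that("difficulty parameters follow the per-level multipliers", {
  expect_equal(difficulty_params(1, cfg),
               list(target_speed = 1, target_size = 1))
  expect_equal(difficulty_params(2, cfg),
               list(target_speed = 1.25, target_size = 0.90))
  # repeated-multiplication oracle for the top level
  sp <- 1; sz <- 1
  for (l in 2:5) {
    sp <- sp * 1.25
    sz <- sz * 0.90
  }
  expect_equal(difficulty_params(5, cfg)$target_speed, sp)
  expect_equal(difficulty_params(5, cfg)$target_size, sz)
  expect_equal(difficulty_params(5, cfg)$target_speed, 2.44140625)
  expect_equal(difficulty_params(5, cfg)$target_size, 0.6561)
  expect_error(difficulty_params(0, cfg), "level")
  expect_error(difficulty_params(6, cfg), "level")
})

test_that("target score sits 5% above the high score with a minimum step", {
  expect_identical(compute_target_score(100, cfg), 105L)
  expect_identical(compute_target_score(0, cfg), 1L)
  expect_identical(compute_target_score(38, cfg), 40L)  # 39.9 rounds half-up
  expect_identical(compute_target_score(10, cfg), 11L)  # 10.5 rounds up
  for (hs in c(0L, 1L, 7L, 19L, 100L, 999L)) {
    expect_gt(compute_target_score(hs, cfg), hs)
  }
  expect_error(compute_target_score(-1, cfg), "high_score")
})

window_state <- function(level, hits, t0 = 100) {
  st <- difficulty_state(level, cfg)
  st$window_time <- t0 + seq_along(hits)
  st$window_hit <- hits
  st
}

test_that("controller steps up above 60%, down below 30%, clamped to 1..5", {
  up <- update_difficulty(window_state(2, rep(c(TRUE, FALSE), c(7, 3))), cfg)
  expect_identical(up$level, 3L)
  expect_equal(up$target_speed, difficulty_params(3, cfg)$target_speed)
  expect_length(up$window_hit, 0)  # window cleared on change

  floor_clamp <- update_difficulty(window_state(1, rep(c(TRUE, FALSE), c(2, 8))), cfg)
  expect_identical(floor_clamp$level, 1L)

  hold <- update_difficulty(window_state(3, rep(c(TRUE, FALSE), c(9, 11))), cfg)
  expect_identical(hold$level, 3L)  # 45% sits between the thresholds
  expect_length(hold$window_hit, 20)

  ceiling_clamp <- update_difficulty(window_state(5, rep(c(TRUE, FALSE), c(19, 1))), cfg)
  expect_identical(ceiling_clamp$level, 5L)
})

test_that("controller waits for the minimum window and ages out old launches", {
  st <- window_state(2, rep(TRUE, 4))
  expect_identical(update_difficulty(st, cfg)$level, 2L)  # < 5 attempts

  # 10 old successes beyond the 60 s span plus 4 recent ones: too few remain
  st <- difficulty_state(2, cfg)
  st$window_time <- c(seq(1, 10), 100 + 1:4)
  st$window_hit <- rep(TRUE, 14)
  out <- update_difficulty(st, cfg, now = 104)
  expect_identical(out$level, 2L)
  expect_length(out$window_hit, 4)
})

test_that("boss chain completes on 7 chained hits and resets after a long gap", {
  boss <- boss_state(cfg)
  boss$active <- TRUE
  t <- 0
  for (i in 1:7) {
    t <- t + 2
    boss <- boss_update(boss, t, cfg)
    expect_identical(boss$completed, i == 7)
    expect_identical(boss$progress, i)
  }

  boss <- boss_state(cfg)
  boss$active <- TRUE
  t <- 0
  for (i in 1:4) {
    t <- t + 2
    boss <- boss_update(boss, t, cfg)
  }
  boss <- boss_update(boss, t + 3.5, cfg)  # gap beyond the 3 s window
  expect_identical(boss$progress, 1L)
  expect_false(boss$completed)

  boss <- boss_state(cfg)
  boss$active <- TRUE
  boss <- boss_update(boss, 10, cfg)
  expect_identical(boss$progress, 1L)  # first hit starts the chain
  expect_false(boss$completed)

  expect_error(boss_update(boss, 5, cfg), "precedes")
  expect_error(boss_update(boss_state(cfg), 1, cfg), "inactive")
})

test_that("register_attempt scores robot hits only and activates power-ups", {
  sc <- score_state(100, cfg)
  sc$session_score <- 12L
  bo <- boss_state(cfg)

  hit <- register_attempt(sc, bo, list(timestamp_s = 1, outcome = "hit_robot"), cfg)
  expect_identical(hit$score$session_score, 13L)

  miss <- register_attempt(sc, bo, list(timestamp_s = 2, outcome = "miss"), cfg)
  expect_identical(miss$score$session_score, 12L)

  pu <- register_attempt(sc, bo, list(timestamp_s = 3, outcome = "hit_powerup",
                                      effect = "rapid_fire"), cfg)
  expect_identical(pu$score$session_score, 12L)
  expect_identical(pu$activated, "rapid_fire")

  expect_error(register_attempt(sc, bo, list(timestamp_s = 4,
                                             outcome = "hit_boss"), cfg),
               "inactive")
})

test_that("boss activates exactly when the score reaches the target", {
  sc <- score_state(9, cfg)  # target 10
  bo <- boss_state(cfg)
  sc$session_score <- 9L
  out <- register_attempt(sc, bo, list(timestamp_s = 1, outcome = "hit_robot"), cfg)
  expect_identical(out$score$session_score, 10L)
  expect_true(out$boss$active)

  # completing the boss refreshes high score and target, frees the boss
  sc2 <- out$score
  bo2 <- out$boss
  for (i in 1:7) {
    out2 <- register_attempt(sc2, bo2,
                             list(timestamp_s = 1 + i, outcome = "hit_boss"),
                             cfg)
    sc2 <- out2$score
    bo2 <- out2$boss
  }
  expect_false(bo2$active)
  expect_identical(bo2$completions, 1L)
  expect_identical(sc2$high_score, 17L)
  expect_identical(sc2$target_score, compute_target_score(17L, cfg))
})

test_that("sessions respect the clock, conserve score, and replay identically", {
  empty <- run_session(policy_never_fires(), cfg, seed = 3)
  expect_identical(nrow(empty$events), 0L)
  expect_identical(empty$final_score, 0L)

  pol <- player_policy(stationary_player(0.8))
  rec <- run_session(pol, cfg, seed = 11, high_score = 400)
  ev <- rec$events
  expect_gt(nrow(ev), 100)
  expect_lte(max(ev$timestamp_s), cfg$session_cap_s)
  expect_false(is.unsorted(ev$timestamp_s))
  expect_true(all(ev$level >= 1 & ev$level <= cfg$n_levels))
  expect_identical(rec$final_score,
                   sum(ev$outcome %in% c("hit_robot", "hit_boss")))
  acc <- session_metrics(rec)$accuracy
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_identical(rec$high_score_end,
                   max(rec$high_score_start, rec$final_score))

  rec2 <- run_session(pol, cfg, seed = 11, high_score = 400)
  expect_identical(rec$events, rec2$events)
  expect_identical(rec$final_score, rec2$final_score)
})

test_that("level changes are separated by the minimum window size", {
  pol <- player_policy(stationary_player(0.7))
  cfg0 <- game_config(powerup_spawn_per_min = 0)
  rec <- run_session(pol, cfg0, seed = 5, high_score = 10000)
  lv <- rec$events$level
  changes <- which(diff(lv) != 0)
  if (length(changes) > 1) {
    expect_true(all(diff(changes) >= cfg0$eval_min_attempts))
  }
  expect_true(all(abs(diff(lv)) <= 1))  # bounded walk, single steps
})

test_that("every boss completion is backed by a chained hit subsequence", {
  pol <- player_policy(player_params())
  rec <- run_session(pol, cfg, seed = 7, high_score = 400)
  expect_gt(rec$boss_completions, 0)
  bt <- rec$events$timestamp_s[rec$events$outcome == "hit_boss"]
  # brute-force scan: some run of 7 consecutive boss hits with gaps <= 3 s
  found <- 0
  for (i in seq_len(max(0, length(bt) - 6))) {
    gaps <- diff(bt[i:(i + 6)])
    if (all(gaps <= cfg$boss_chain_window_s)) found <- found + 1
  }
  expect_gte(found, rec$boss_completions)
  expect_gt(found, 0)
})
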