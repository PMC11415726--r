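test_that("phase summaries reproduce the COPM table arithmetic", {
  pre_perf <- c(8, 6, 7, 9, 9)
  s <- phase_summary(pre_perf)
  expect_equal(s$mean, 7.8)
  expect_equal(round(s$sd, 1), 1.2)

  post_sat <- c(10, 7, 8, 10, 10)
  s2 <- phase_summary(post_sat)
  expect_equal(s2$mean, 9)
  expect_equal(round(s2$sd, 1), 1.3)

  expect_equal(phase_summary(c(5, 5, 5)),
               list(mean = 5, sd = 0, n = 3L))
  expect_equal(phase_summary(c(2, 4), sd_mode = "sample")$sd, sd(c(2, 4)))
  expect_error(phase_summary(numeric(0)), "value")
  expect_error(phase_summary(7, sd_mode = "sample"), "two")
})

test_that("percent change matches the reported task-performance gains", {
  expect_equal(round(percent_change(728.3, 1020.0)), 40)
  expect_equal(round(percent_change(25.1, 34.0), 1), 35.5)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 3), "zero")
  for (p in c(-50, -1, 0.5, 12, 250)) {
    expect_equal(percent_change(3.7, 3.7 * (1 + p / 100)), p,
                 tolerance = 1e-9)
  }
})

test_that("Cohen's d follows the pooled formula and its bands", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_identical(cohens_d(c(1, 2, 3), c(1, 2, 3))$band, "negligible")

  # constructed so the hand-computed pooled d is exactly 2
  a <- c(0, 0, 0, 0)
  jitter <- c(-1.5, -0.5, 0.5, 1.5)
  b <- sqrt(2) + jitter / sd(jitter)   # mean sqrt(2), sample SD 1
  s_pooled <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal((mean(b) - mean(a)) / s_pooled, 2, tolerance = 1e-12)
  expect_equal(cohens_d(a, b)$d, 2, tolerance = 1e-9)
  expect_identical(cohens_d(a, b)$band, "large")

  expect_identical(effect_band(0.85), "large")
  expect_identical(effect_band(-0.85), "large")
  expect_identical(effect_band(c(0.1, 0.2, 0.5, 0.79, 0.8)),
                   c("negligible", "small", "medium", "medium", "large"))

  # baseline-SD denominator mode
  expect_equal(cohens_d(c(0, 2), c(5), mode = "baseline_sd")$d,
               4 / sd(c(0, 2)))
  # single post value against a 3-point baseline degenerates to baseline SD
  base <- c(10, 12, 14)
  expect_equal(cohens_d(base, 16)$d, (16 - 12) / sd(base))

  expect_error(cohens_d(c(1, 1, 1), c(1, 1)), "zero spread")
})

test_that("Cohen's d is antisymmetric and scale invariant", {
  withr::with_seed(42, {
    for (i in 1:10) {
      a <- rnorm(sample(3:8, 1))
      b <- rnorm(sample(3:8, 1), mean = 1)
      d_ab <- cohens_d(a, b)$d
      expect_equal(cohens_d(b, a)$d, -d_ab, tolerance = 1e-12)
      k <- runif(1, 0.5, 10)
      m <- rnorm(1)
      expect_equal(cohens_d(k * a + m, k * b + m)$d, d_ab,
                   tolerance = 1e-9)
    }
  })
})

test_that("phase trends equal the normal-equations solution", {
  expect_equal(phase_trend(c(1, 2, 3, 4))$slope, 1)
  expect_equal(phase_trend(c(7, 7, 7))$slope, 0)
  withr::with_seed(7, {
    for (i in 1:5) {
      y <- rnorm(10)
      x <- seq_along(y)
      X <- cbind(1, x)
      beta <- solve(t(X) %*% X, t(X) %*% y)  # normal-equations oracle
      tr <- phase_trend(phase_series(y, "intervention", session_index = x))
      expect_equal(tr$slope, unname(beta[2, 1]), tolerance = 1e-9)
      expect_equal(tr$intercept, unname(beta[1, 1]), tolerance = 1e-9)
    }
  })
  expect_error(phase_trend(5), "two")
})

test_that("COPM analysis counts clinically important goal changes", {
  tab <- read_copm_table(copm_fixture_path())
  an <- copm_analyze(tab)
  expect_equal(an$goals$performance_delta, c(2, 2, 2, 1, 1))
  expect_identical(unname(an$n_goals_mcid["performance"]), 3L)
  expect_equal(unname(an$mean_improvement["performance"]), 1.6)
  expect_equal(unname(an$mean_improvement["satisfaction"]), 1.6)

  sm <- an$summary
  expect_equal(sm$mean[sm$scale == "performance" & sm$phase == "pre"], 7.8)
  expect_equal(sm$mean[sm$scale == "performance" & sm$phase == "post"], 9.4)

  # consistency with phase_summary across operations
  expect_equal(unname(an$mean_improvement["performance"]),
               phase_summary(tab$performance_post)$mean -
                 phase_summary(tab$performance_pre)$mean)

  flat <- tab
  flat$performance_post <- flat$performance_pre
  flat$satisfaction_post <- flat$satisfaction_pre
  an2 <- copm_analyze(flat)
  expect_true(all(an2$goals$performance_delta == 0))
  expect_identical(unname(an2$n_goals_mcid["performance"]), 0L)

  broken <- tab
  broken$performance_post[1] <- NA
  expect_error(copm_analyze(broken), "missing")
})

test_that("phase_stats assembles summaries and effects per metric", {
  metrics <- data.frame(
    session_index = 1:7,
    phase = c("baseline", "baseline", "baseline", "intervention",
              "intervention", "intervention", "post"),
    metric = "accuracy",
    value = c(0.60, 0.65, 0.62, 0.80, 0.82, 0.85, 0.90)
  )
  out <- phase_stats(metrics)
  expect_identical(nrow(out$summary), 3L)
  expect_true(is.na(out$summary$slope[out$summary$phase == "post"]))
  expect_identical(nrow(out$effects), 2L)
  d_direct <- cohens_d(metrics$value[1:3], metrics$value[7])$d
  expect_equal(out$effects$d[out$effects$contrast == "baseline_vs_post"],
               d_direct)
})
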