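# Single-case three-phase statistics: phase summaries, percent change,
# Cohen's d with interpretation bands, per-phase trend lines, and COPM
# goal-table analysis.

#' Phase-tagged metric series
#'
#' Ordered values of one metric within one study phase.
#'
#' @param values Finite numeric values in session order.
#' @param phase `"baseline"`, `"intervention"` or `"post"`.
#' @param metric Metric identifier (free text).
#' @param session_index Optional session indices (defaults to `1..n`).
#' @return Object of class `phase_series`.
#' @export
phase_series <- function(values, phase = "baseline", metric = "metric",
                         session_index = seq_along(values)) {
  if (length(values) == 0 || any(!is.finite(values))) {
    stop_domain("phase values must be a nonempty finite numeric vector")
  }
  phase <- match.arg(phase, c("baseline", "intervention", "post"))
  structure(list(values = as.numeric(values), phase = phase, metric = metric,
                 session_index = as.numeric(session_index)),
            class = "phase_series")
}

as_phase_values <- function(x) {
  if (inherits(x, "phase_series")) x$values else as.numeric(x)
}

#' Phase mean and standard deviation
#'
#' Arithmetic mean and SD of a phase. The default SD mode is `"population"`
#' (divide by n), which is the convention that reproduces the printed
#' COPM summary SDs of the study this package models; `"sample"` (divide by
#' n - 1) is available.
#'
#' @param series A [phase_series()] or numeric vector.
#' @param sd_mode `"population"` or `"sample"`.
#' @return List with `mean`, `sd`, `n`.
#' @examples
#' phase_summary(c(8, 6, 7, 9, 9))  # mean 7.8, population SD ~1.17
#' @export
phase_summary <- function(series, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  v <- as_phase_values(series)
  n <- length(v)
  if (n < 1) {
    stop_domain("phase_summary() needs at least one value")
  }
  if (sd_mode == "sample" && n < 2) {
    stop_domain("sample SD needs at least two values")
  }
  s <- if (n == 1) {
    if (sd_mode == "population") 0 else NA_real_
  } else if (sd_mode == "population") {
    sqrt(sum((v - mean(v))^2) / n)
  } else {
    stats::sd(v)
  }
  list(mean = mean(v), sd = s, n = n)
}

#' Percent change from a reference value
#'
#' `100 * (value - reference) / reference`.
#'
#' @param reference Nonzero reference value.
#' @param value New value.
#' @return Percent change (vectorised over `value`).
#' @examples
#' percent_change(728.3, 1020.0)  # ~40.0
#' percent_change(25.1, 34.0)     # ~35.5
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) {
    stop_domain("percent change is undefined for a zero reference")
  }
  100 * (value - reference) / reference
}

#' Interpretation band of a standardised effect
#'
#' Conventional bands on `|d|`: below 0.2 negligible, 0.2 to under 0.5
#' small, 0.5 to under 0.8 medium, 0.8 and above large.
#'
#' @param d Effect size(s).
#' @return Character vector of band labels.
#' @export
effect_band <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
  ifelse(a < 0.5, "small",
  ifelse(a < 0.8, "medium", "large")))
}

#' Cohen's d between two phases
#'
#' Standardised mean difference `(mean_b - mean_a) / s`, where `s` is either
#' the pooled SD `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) /
#' (n_a + n_b - 2))` (sample variances; mode `"pooled"`) or the baseline
#' phase's SD (mode `"baseline_sd"`). With a single value in one phase the
#' pooled formula degenerates gracefully: that phase contributes zero to the
#' numerator of the pooled variance, so a 3-point baseline against one post
#' value is standardised by the baseline spread.
#'
#' @param phase_a,phase_b [phase_series()] or numeric vectors (a = reference
#'   phase, b = comparison phase).
#' @param mode `"pooled"` or `"baseline_sd"`.
#' @return List (class `effect_size`) with `d`, `band`, `denominator_mode`,
#'   `mean_a`, `mean_b`, `s`.
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6))
#' @export
cohens_d <- function(phase_a, phase_b, mode = c("pooled", "baseline_sd")) {
  mode <- match.arg(mode)
  a <- as_phase_values(phase_a)
  b <- as_phase_values(phase_b)
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 1 || n_b < 1) {
    stop_domain("each phase needs at least one value")
  }
  if (mode == "pooled") {
    if (n_a + n_b < 3) {
      stop_domain("pooled mode needs at least three values in total")
    }
    ss_a <- if (n_a > 1) (n_a - 1) * stats::var(a) else 0
    ss_b <- if (n_b > 1) (n_b - 1) * stats::var(b) else 0
    s <- sqrt((ss_a + ss_b) / (n_a + n_b - 2))
  } else {
    if (n_a < 2) {
      stop_domain("baseline_sd mode needs at least two baseline values")
    }
    s <- stats::sd(a)
  }
  if (!is.finite(s) || s == 0) {
    stop_domain("effect size undefined: zero spread in the denominator")
  }
  d <- (mean(b) - mean(a)) / s
  structure(list(d = d, band = effect_band(d), denominator_mode = mode,
                 mean_a = mean(a), mean_b = mean(b), s = s),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s; %s denominator)\n",
              x$d, x$band, x$denominator_mode))
  invisible(x)
}

#' Within-phase trend line
#'
#' Ordinary least-squares slope and intercept of a phase's values over its
#' session indices (the per-phase trend line drawn in single-case plots).
#'
#' @param series A [phase_series()] or numeric vector.
#' @return List with `slope`, `intercept`, `n`.
#' @export
phase_trend <- function(series) {
  v <- as_phase_values(series)
  idx <- if (inherits(series, "phase_series")) {
    series$session_index
  } else {
    seq_along(v)
  }
  if (length(v) < 2) {
    stop_domain("a trend needs at least two values")
  }
  fit <- stats::lm(v ~ idx)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), n = length(v))
}

#' Analyse a COPM goal table
#'
#' Per-goal pre/post scores and deltas on both COPM scales (performance and
#' satisfaction/perception), phase means and SDs (population mode, matching
#' the printed convention), mean improvement per scale, and the number of
#' goals reaching the minimal clinically important difference.
#'
#' @param table COPM data.frame as from [read_copm_table()].
#' @param mcid Minimal clinically important difference (default 2 points).
#' @return List (class `copm_analysis`) with `goals` (per-goal deltas),
#'   `summary` (per scale x phase mean/SD), `mean_improvement`, and
#'   `n_goals_mcid` per scale.
#' @export
copm_analyze <- function(table, mcid = 2) {
  need <- c("goal", "performance_pre", "performance_post",
            "satisfaction_pre", "satisfaction_post")
  if (!all(need %in% names(table))) {
    stop_domain("COPM table must have columns: %s",
                paste(need, collapse = ", "))
  }
  if (any(!stats::complete.cases(table[need]))) {
    stop_domain("COPM table has missing cells")
  }
  goals <- data.frame(
    goal = table$goal,
    performance_pre = table$performance_pre,
    performance_post = table$performance_post,
    performance_delta = table$performance_post - table$performance_pre,
    satisfaction_pre = table$satisfaction_pre,
    satisfaction_post = table$satisfaction_post,
    satisfaction_delta = table$satisfaction_post - table$satisfaction_pre,
    stringsAsFactors = FALSE
  )
  summarise <- function(v) phase_summary(v, sd_mode = "population")
  cells <- list(
    performance_pre = summarise(table$performance_pre),
    performance_post = summarise(table$performance_post),
    satisfaction_pre = summarise(table$satisfaction_pre),
    satisfaction_post = summarise(table$satisfaction_post)
  )
  summary <- data.frame(
    scale = c("performance", "performance", "satisfaction", "satisfaction"),
    phase = c("pre", "post", "pre", "post"),
    mean = vapply(cells, `[[`, numeric(1), "mean"),
    sd = vapply(cells, `[[`, numeric(1), "sd"),
    row.names = NULL
  )
  structure(list(
    goals = goals,
    summary = summary,
    mean_improvement = c(performance = mean(goals$performance_delta),
                         satisfaction = mean(goals$satisfaction_delta)),
    n_goals_mcid = c(performance = sum(goals$performance_delta >= mcid),
                     satisfaction = sum(goals$satisfaction_delta >= mcid)),
    mcid = mcid
  ), class = "copm_analysis")
}

#' @export
print.copm_analysis <- function(x, ...) {
  cat("<copm_analysis>\n")
  cat(sprintf("  performance: %.1f -> %.1f (mean improvement %.1f, %d/%d goals >= %g)\n",
              x$summary$mean[1], x$summary$mean[2],
              x$mean_improvement[["performance"]],
              x$n_goals_mcid[["performance"]], nrow(x$goals), x$mcid))
  cat(sprintf("  satisfaction: %.1f -> %.1f (mean improvement %.1f, %d/%d goals >= %g)\n",
              x$summary$mean[3], x$summary$mean[4],
              x$mean_improvement[["satisfaction"]],
              x$n_goals_mcid[["satisfaction"]], nrow(x$goals), x$mcid))
  invisible(x)
}

#' Three-phase statistics for a metrics table
#'
#' Runs the single-case analysis for every metric in a long-format metrics
#' table: per-phase mean/SD/n, per-phase OLS trend slope, and Cohen's d for
#' baseline-to-intervention and baseline-to-post contrasts.
#'
#' @param metrics Long data.frame with columns `session_index`, `phase`
#'   (baseline/intervention/post), `metric`, `value`.
#' @param sd_mode SD convention for the phase summaries.
#' @param d_mode Denominator mode for [cohens_d()].
#' @return List with `summary` (metric x phase rows with mean, sd, n,
#'   slope) and `effects` (metric rows with d and band per contrast).
#' @export
phase_stats <- function(metrics, sd_mode = c("population", "sample"),
                        d_mode = c("pooled", "baseline_sd")) {
  sd_mode <- match.arg(sd_mode)
  d_mode <- match.arg(d_mode)
  need <- c("session_index", "phase", "metric", "value")
  if (!all(need %in% names(metrics))) {
    stop_domain("metrics table must have columns: %s",
                paste(need, collapse = ", "))
  }
  phases <- c("baseline", "intervention", "post")
  summary_rows <- list()
  effect_rows <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m, ]
    series <- list()
    for (ph in phases) {
      v <- sub$value[sub$phase == ph]
      idx <- sub$session_index[sub$phase == ph]
      if (length(v) == 0) next
      series[[ph]] <- phase_series(v, ph, m, idx)
      sm <- phase_summary(series[[ph]], sd_mode)
      slope <- if (length(v) >= 2) phase_trend(series[[ph]])$slope else NA_real_
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        metric = m, phase = ph, n = sm$n, mean = sm$mean, sd = sm$sd,
        slope = slope, stringsAsFactors = FALSE
      )
    }
    for (target in c("intervention", "post")) {
      if (is.null(series$baseline) || is.null(series[[target]])) next
      es <- tryCatch(cohens_d(series$baseline, series[[target]], d_mode),
                     error = function(e) NULL)
      if (is.null(es)) next
      effect_rows[[length(effect_rows) + 1]] <- data.frame(
        metric = m, contrast = paste0("baseline_vs_", target),
        d = es$d, band = es$band, denominator = d_mode,
        stringsAsFactors = FALSE
      )
    }
  }
  list(summary = do.call(rbind, summary_rows),
       effects = if (length(effect_rows)) do.call(rbind, effect_rows) else NULL)
}
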