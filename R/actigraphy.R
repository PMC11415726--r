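# Open activity-counts pipeline: band-pass filter, rectification, dead-band,
# clipping, quantisation and epoch summation, followed by intensity
# classification against counts-per-minute cutoffs. Re-implements the
# function of commercial count-processing software with every constant
# exposed; exact equivalence with any proprietary filter is not claimed.

#' Activity-counts pipeline configuration
#'
#' Constants of the raw-acceleration-to-counts transform. Defaults follow
#' the published open specification of actigraph-style counts: a 0.25-2.5 Hz
#' body-movement band, a 0.068 g dead-band, a 2.13 g clip ceiling, and a
#' 1/128 g quantum, summed over 60-second epochs.
#'
#' @param epoch_length_s Epoch length in seconds (default 60).
#' @param band_low_hz,band_high_hz Band-pass corner frequencies in Hz
#'   (defaults 0.25 and 2.5).
#' @param dead_band_g Amplitude below which rectified acceleration is
#'   ignored (default 0.068 g).
#' @param clip_g Amplitude ceiling (default 2.13 g).
#' @param quantum_g Quantisation step (default 1/128 g).
#' @param axis_mode `"vertical"` (single axis, the conventional cutoff
#'   definition; here the z axis) or `"vector_magnitude"`.
#' @return Object of class `counts_config`.
#' @export
counts_config <- function(epoch_length_s = 60,
                          band_low_hz = 0.25,
                          band_high_hz = 2.5,
                          dead_band_g = 0.068,
                          clip_g = 2.13,
                          quantum_g = 1 / 128,
                          axis_mode = c("vertical", "vector_magnitude")) {
  axis_mode <- match.arg(axis_mode)
  check_scalar(epoch_length_s, "epoch_length_s", lo = 1e-9)
  check_scalar(band_low_hz, "band_low_hz", lo = 1e-9)
  check_scalar(band_high_hz, "band_high_hz", lo = 1e-9)
  if (!(band_low_hz < band_high_hz)) {
    stop_domain("band_low_hz must be below band_high_hz")
  }
  check_scalar(dead_band_g, "dead_band_g", lo = 0)
  check_scalar(clip_g, "clip_g", lo = 1e-9)
  check_scalar(quantum_g, "quantum_g", lo = 1e-12)
  structure(list(epoch_length_s = epoch_length_s,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 dead_band_g = dead_band_g, clip_g = clip_g,
                 quantum_g = quantum_g, axis_mode = axis_mode),
            class = "counts_config")
}

#' Intensity cutoff set
#'
#' Counts-per-minute thresholds separating sedentary, light, moderate and
#' vigorous activity. The default is the Evenson youth convention
#' (sedentary <= 100, light <= 2295, moderate <= 4011 cpm), shipped here as
#' overridable configuration. Class intervals are closed above: a cpm equal
#' to a threshold maps to the lower class.
#'
#' @param name Label for the set.
#' @param sedentary_max,light_max,moderate_max Thresholds in counts/min,
#'   strictly increasing.
#' @return Object of class `cutoff_set`.
#' @export
cutoff_set <- function(name = "evenson_youth",
                       sedentary_max = 100,
                       light_max = 2295,
                       moderate_max = 4011) {
  if (!(sedentary_max < light_max && light_max < moderate_max)) {
    stop_domain("cutoffs must satisfy sedentary_max < light_max < moderate_max")
  }
  structure(list(name = name, sedentary_max = sedentary_max,
                 light_max = light_max, moderate_max = moderate_max),
            class = "cutoff_set")
}

#' Compute per-epoch activity counts from 30 Hz acceleration
#'
#' Per axis: remove the mean, band-pass filter (3rd-order zero-phase
#' Butterworth over the configured body-movement band, which also removes
#' the gravity/DC component), rectify, subtract the dead-band (floored at
#' zero), clip, quantise by the quantum, and sum per epoch. The band-pass is
#' applied to the whole recording before epoching, so epoch boundaries
#' introduce no filter transients and epoch sums are a pure partition of the
#' per-sample count stream.
#'
#' A trailing partial epoch is kept; its counts-per-minute value is scaled by
#' its actual duration.
#'
#' @param series An [accel_series()] at 30 Hz.
#' @param config A [counts_config()].
#' @return data.frame with `epoch_index`, `start_s`, `counts_x`, `counts_y`,
#'   `counts_z`, `cpm` (per the configured `axis_mode`).
#' @export
compute_counts <- function(series, config = counts_config()) {
  stopifnot(inherits(series, "accel_series"),
            inherits(config, "counts_config"))
  if (abs(series$sample_rate - 30) > 1e-9) {
    stop_domain("compute_counts() expects a 30 Hz series (got %g Hz); downsample first",
                series$sample_rate)
  }
  fs <- series$sample_rate
  nyq <- fs / 2
  if (config$band_high_hz >= nyq) {
    stop_domain("band_high_hz must be below the Nyquist frequency %g", nyq)
  }
  n <- nrow(series$samples)
  if (n == 0) {
    stop_domain("empty acceleration series")
  }
  bf <- signal::butter(3, c(config$band_low_hz, config$band_high_hz) / nyq,
                       type = "pass")
  per_sample <- apply(series$samples, 2, function(col) {
    col <- col - mean(col)
    filtered <- signal::filtfilt(bf, col)
    mag <- abs(filtered)
    mag <- pmax(mag - config$dead_band_g, 0)
    mag <- pmin(mag, config$clip_g)
    floor(mag / config$quantum_g)
  })
  per_sample <- matrix(per_sample, ncol = 3)

  epoch_samples <- round(config$epoch_length_s * fs)
  idx <- rep(seq_len(ceiling(n / epoch_samples)), each = epoch_samples,
             length.out = n)
  sums <- rowsum(per_sample, idx)
  n_in_epoch <- as.vector(rowsum(rep(1, n), idx))
  epoch_sec <- n_in_epoch / fs

  counts <- data.frame(
    epoch_index = seq_len(nrow(sums)),
    start_s = (seq_len(nrow(sums)) - 1) * config$epoch_length_s,
    counts_x = sums[, 1],
    counts_y = sums[, 2],
    counts_z = sums[, 3]
  )
  axis_counts <- if (config$axis_mode == "vertical") {
    counts$counts_z
  } else {
    sqrt(counts$counts_x^2 + counts$counts_y^2 + counts$counts_z^2)
  }
  counts$cpm <- axis_counts * 60 / epoch_sec
  counts
}

#' Label epochs with an intensity class
#'
#' Compares each epoch's counts-per-minute value against the cutoff set.
#' Intervals are closed above: `cpm <= sedentary_max` is sedentary,
#' `cpm <= light_max` light, `cpm <= moderate_max` moderate, above that
#' vigorous. MVPA is moderate plus vigorous.
#'
#' @param epochs data.frame from [compute_counts()] (needs a `cpm` column).
#' @param cutoffs A [cutoff_set()].
#' @return `epochs` with an added `intensity` factor column.
#' @export
classify_intensity <- function(epochs, cutoffs = cutoff_set()) {
  stopifnot(is.data.frame(epochs), "cpm" %in% names(epochs),
            inherits(cutoffs, "cutoff_set"))
  lv <- c("sedentary", "light", "moderate", "vigorous")
  cls <- ifelse(epochs$cpm <= cutoffs$sedentary_max, "sedentary",
         ifelse(epochs$cpm <= cutoffs$light_max, "light",
         ifelse(epochs$cpm <= cutoffs$moderate_max, "moderate", "vigorous")))
  epochs$intensity <- factor(cls, levels = lv)
  epochs
}

#' Session intensity summary
#'
#' Fractions of a session's epochs spent sedentary, in light physical
#' activity (LPA) and in moderate-to-vigorous physical activity (MVPA =
#' moderate + vigorous), in percent. The three always sum to 100.
#'
#' @param epochs data.frame with an `intensity` column from
#'   [classify_intensity()].
#' @return One-row data.frame `pct_sedentary`, `pct_lpa`, `pct_mvpa`.
#' @export
session_intensity_summary <- function(epochs) {
  stopifnot(is.data.frame(epochs))
  if (nrow(epochs) == 0) {
    stop_domain("intensity summary needs at least one epoch")
  }
  if (is.null(epochs$intensity)) {
    stop_domain("epochs must be classified first (see classify_intensity)")
  }
  n <- nrow(epochs)
  data.frame(
    pct_sedentary = 100 * sum(epochs$intensity == "sedentary") / n,
    pct_lpa = 100 * sum(epochs$intensity == "light") / n,
    pct_mvpa = 100 * sum(epochs$intensity %in% c("moderate", "vigorous")) / n
  )
}

#' Full intensity pipeline for one raw recording
#'
#' Convenience chain: down-sample a 120 Hz recording to 30 Hz, compute
#' epoch counts, classify intensities and summarise the session.
#'
#' @param series An [accel_series()] (any rate divisible by 30).
#' @param config A [counts_config()].
#' @param cutoffs A [cutoff_set()].
#' @return List with `epochs` (classified counts) and `summary` (the
#'   [session_intensity_summary()] row).
#' @export
intensity_pipeline <- function(series, config = counts_config(),
                               cutoffs = cutoff_set()) {
  if (series$sample_rate != 30) {
    series <- downsample_accel(series, 30)
  }
  epochs <- classify_intensity(compute_counts(series, config), cutoffs)
  list(epochs = epochs, summary = session_intensity_summary(epochs))
}
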