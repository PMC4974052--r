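#' Mean amplitude in a time window
#'
#' Averages the samples whose timestamps fall in the half-open window
#' `[start, end)`. For an `lfp_set` the result is one mean per trial; for a
#' `source_waveform` or a bare numeric vector (with `sampling_rate` and `t0`)
#' a single mean.
#'
#' @param x An `lfp_set`, `source_waveform`, or numeric sample vector.
#' @param window `c(start, end)` in seconds on the object's time base.
#' @param ... Passed to methods.
#' @return Numeric: per-trial means (`lfp_set`) or a single mean.
#' @export
window_mean <- function(x, window, ...) UseMethod("window_mean")

#' @rdname window_mean
#' @param sampling_rate,t0 Time base of a bare sample vector.
#' @export
window_mean.default <- function(x, window, sampling_rate, t0 = 0, ...) {
  check_window(window)
  t <- t0 + (seq_along(x) - 1) / sampling_rate
  idx <- in_window(t, window)
  if (!any(idx)) stop("window [", window[1], ", ", window[2],
                      ") contains no samples")
  mean(x[idx])
}

#' @rdname window_mean
#' @export
window_mean.lfp_set <- function(x, window, ...) {
  check_window(window)
  idx <- in_window(x$t, window)
  if (!any(idx)) stop("window contains no samples")
  rowMeans(x$samples[, idx, drop = FALSE])
}

#' @rdname window_mean
#' @export
window_mean.source_waveform <- function(x, window, ...) {
  window_mean.default(x$samples, window, x$sampling_rate, x$t0)
}

#' High- minus low-load LFP difference with permutation p-value
#'
#' The difference of mean LFP amplitude between high- and low-load trials in
#' a window (by default the final 500 ms of the delay), tested by a
#' two-sample label permutation on the per-trial window means with the
#' difference of means as statistic.
#'
#' @param lfp An `lfp_set` from [simulate_lfp()].
#' @param trials Trial table matching the traces (`trial_id` aligned).
#' @param window Window name or `c(start, end)`.
#' @param config A [perm_config()]; the statistic is forced to
#'   `"difference_of_means"`.
#' @param context Behavioral context filter (default `"correct"`).
#' @param levels Condition labels to contrast, minuend first.
#' @return A `perm_result` augmented with `difference`, `mean_high`,
#'   `mean_low`, `window`, `n_high`, `n_low`.
#' @export
high_low_lfp_diff <- function(lfp, trials, window = "delay_final",
                              config = perm_config(), context = "correct",
                              levels = c("high", "low")) {
  trials <- filter_context(trials, context)
  win <- resolve_window(window, trials)
  rows <- match(trials$trial_id, lfp$trial_id)
  if (anyNA(rows)) stop("trials without matching LFP traces")
  means <- window_mean(lfp, win)[rows]
  x <- means[trials$load == levels[1]]
  y <- means[trials$load == levels[2]]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 trials per condition")
  config$statistic <- "difference_of_means"
  res <- perm_test_two_sample(x, y, config)
  res$difference <- mean(x) - mean(y)
  res$mean_high <- mean(x)
  res$mean_low <- mean(y)
  res$window <- win
  res$n_high <- length(x)
  res$n_low <- length(y)
  res
}

#' Delay minus baseline LFP difference with paired permutation p-value
#'
#' Subtracts each trial's mean baseline amplitude (500 ms before S1) from its
#' mean amplitude in the final 500 ms of the delay, for trials of one load,
#' and tests the mean paired difference by sign-flip permutation.
#'
#' @param lfp An `lfp_set`.
#' @param trials Trial table.
#' @param load Condition label selecting the trials.
#' @param config A [perm_config()].
#' @param context Behavioral context filter (default `"correct"`).
#' @return A `perm_result` augmented with `difference` and `n_trials`.
#' @export
delay_baseline_lfp_diff <- function(lfp, trials, load = "high",
                                    config = perm_config(),
                                    context = "correct") {
  trials <- filter_context(trials, context)
  trials <- trials[trials$load == load, , drop = FALSE]
  if (nrow(trials) < 2) stop("need >= 2 trials of load '", load, "'")
  wins <- analysis_windows(trials)
  rows <- match(trials$trial_id, lfp$trial_id)
  if (anyNA(rows)) stop("trials without matching LFP traces")
  d <- window_mean(lfp, wins$delay_final)[rows] -
       window_mean(lfp, wins$baseline)[rows]
  res <- perm_test_signflip(d, config)
  res$difference <- mean(d)
  res$n_trials <- nrow(trials)
  res
}

#' Zero-phase high-pass filter control
#'
#' High-pass filters traces with a 4th-order Butterworth applied forward and
#' backward (zero phase). A 4-Hz cutoff removes sustained offsets such as
#' delay-period DC shifts while leaving faster components essentially intact,
#' so load differences that survive this control are not due to sustained
#' potentials.
#'
#' @param x An `lfp_set` or numeric sample vector.
#' @param cutoff High-pass cutoff in Hz (must be below the Nyquist
#'   frequency).
#' @param sampling_rate Required for bare numeric input.
#' @return The filtered object, same shape as the input.
#' @export
highpass_control <- function(x, cutoff = 4, sampling_rate = NULL) {
  if (inherits(x, "lfp_set")) {
    sr <- x$sampling_rate
  } else {
    if (is.null(sampling_rate)) stop("'sampling_rate' needed for numeric input")
    sr <- sampling_rate
  }
  if (sr <= 2 * cutoff) stop("'cutoff' must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (sr / 2), type = "high")
  if (inherits(x, "lfp_set")) {
    x$samples <- t(apply(x$samples, 1, function(row) {
      signal::filtfilt(bf, row)
    }))
    x
  } else {
    signal::filtfilt(bf, x)
  }
}
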