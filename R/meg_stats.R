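#' Delay window set for source-waveform statistics
#'
#' Three consecutive 500-ms windows partitioned backward from S2 onset (so
#' the last window is the final 500 ms of the delay), plus the pre-S1
#' baseline windows: 500 ms for elevation tests and 300 ms for offset
#' correction. Time 0 is S1 onset.
#'
#' @param soa S1-to-S2 onset interval (s).
#' @param n_windows Number of delay windows.
#' @param width Window width (s).
#' @return List with `delay` (list of `c(start, end)` windows, earliest
#'   first), `baseline` (500 ms pre-S1), `offset_baseline` (300 ms pre-S1).
#' @export
delay_window_set <- function(soa = 2.0, n_windows = 3, width = 0.5) {
  starts <- soa - width * (n_windows:1)
  if (starts[1] < 0) stop("windows extend before S1 onset")
  list(
    delay = lapply(seq_len(n_windows),
                   function(i) c(starts[i], starts[i] + width)),
    baseline = c(-0.5, 0),
    offset_baseline = c(-0.3, 0)
  )
}

#' Baseline-offset correction of a signed waveform
#'
#' Subtracts the mean amplitude over the 300-ms interval directly before S1.
#' Intended for signed sensor-space-like signals; source strengths are
#' strictly positive magnitudes and must not be offset-corrected (the
#' correction belongs before source analysis).
#'
#' @param waveform A `source_waveform`-shaped object (fields `samples`,
#'   `sampling_rate`, `t0` with time 0 at S1 onset).
#' @param interval Length of the pre-S1 interval (s).
#' @return The waveform with the pre-S1 mean subtracted.
#' @export
baseline_offset_correct <- function(waveform, interval = 0.3) {
  if (waveform$t0 > -interval + 1e-9) {
    stop("waveform does not cover the ", interval * 1000, "-ms pre-S1 interval")
  }
  offset <- window_mean.default(waveform$samples, c(-interval, 0),
                                waveform$sampling_rate, waveform$t0)
  waveform$samples <- waveform$samples - offset
  waveform
}

#' Grand geometric-mean waveform across subjects
#'
#' Log-transforms each subject's strictly positive source waveform,
#' arithmetically averages the logs pointwise across subjects, and
#' back-transforms by exponentiation — the geometric mean, suited to
#' multiplicative between-subject variability and plotted on a logarithmic
#' axis.
#'
#' @param waveforms List of `source_waveform`s from one condition, equal
#'   time bases.
#' @return A `source_waveform` (subject `"grand"`) with an `n_subjects`
#'   field.
#' @export
grand_geomean <- function(waveforms) {
  if (!length(waveforms)) stop("no waveforms")
  lens <- vapply(waveforms, function(w) length(w$samples), 0L)
  if (length(unique(lens)) != 1L) stop("waveforms differ in length")
  mat <- vapply(waveforms, function(w) {
    if (any(w$samples <= 0)) stop("source waveforms must be strictly positive")
    w$samples
  }, numeric(lens[1]))
  out <- waveforms[[1]]
  out$samples <- exp(rowMeans(log(mat)))
  out$subject_id <- "grand"
  out$n_subjects <- length(waveforms)
  out
}

match_subjects <- function(high, low) {
  sh <- vapply(high, function(w) w$subject_id, "")
  sl <- vapply(low, function(w) w$subject_id, "")
  if (length(sh) != length(sl) || !setequal(sh, sl) || anyDuplicated(sh)) {
    stop("conditions must contain the same subjects exactly once each")
  }
  low[match(sh, sl)]
}

#' Windowed source-strength ratio tests across subjects
#'
#' For each delay window, computes each subject's log ratio of mean source
#' strength in the high- to that in the low-load condition and tests the mean
#' log ratio against zero by sign-flip permutation (two-tailed), with
#' Bonferroni correction over the windows. Ratios make the test invariant to
#' per-subject multiplicative scaling.
#'
#' @param high_waveforms,low_waveforms Lists of `source_waveform`s, one per
#'   subject, paired by `subject_id`.
#' @param windows A [delay_window_set()] (or list of windows under `$delay`).
#' @param m Bonferroni factor (default the number of windows).
#' @param config A [perm_config()].
#' @param alpha Family-wise level for the corrected decisions.
#' @return A `data.frame` with one row per window: `window`, `start`, `end`,
#'   `ratio` (geometric mean of subject ratios), `p`, `p_adjusted`,
#'   `significant`.
#' @export
window_ratio_test <- function(high_waveforms, low_waveforms,
                              windows = delay_window_set(), m = NULL,
                              config = perm_config(), alpha = 0.05) {
  if (length(high_waveforms) < 2) stop("need >= 2 subjects")
  low_waveforms <- match_subjects(high_waveforms, low_waveforms)
  wins <- if (!is.null(windows$delay)) windows$delay else windows
  if (is.null(m)) m <- length(wins)
  p <- numeric(length(wins))
  ratio <- numeric(length(wins))
  for (i in seq_along(wins)) {
    lr <- mapply(function(h, l) {
      log(window_mean(h, wins[[i]]) / window_mean(l, wins[[i]]))
    }, high_waveforms, low_waveforms)
    res <- perm_test_signflip(lr, config)
    p[i] <- res$p_value
    ratio[i] <- exp(mean(lr))
  }
  adj <- bonferroni(p, m, alpha)
  data.frame(
    window = seq_along(wins),
    start = vapply(wins, `[`, 0, 1), end = vapply(wins, `[`, 0, 2),
    ratio = ratio, p = p, p_adjusted = adj$p_adjusted,
    significant = adj$significant
  )
}

#' Sustained delay elevation test
#'
#' Tests whether source strength during the delay exceeds the pre-S1 baseline
#' level: each subject contributes the log ratio of mean delay strength to
#' mean strength in the 500 ms before S1, and the mean log ratio is tested by
#' a one-tailed (greater) sign-flip permutation.
#'
#' @param waveforms List of `source_waveform`s, one per subject (a single
#'   condition).
#' @param delay_window `c(start, end)`; defaults to the full delay of a
#'   2-s-SOA design, `[0.1, 2)`.
#' @param baseline_window `c(start, end)` pre-S1 window.
#' @param config A [perm_config()]; the tail is forced to `"one_greater"`.
#' @return A `perm_result` augmented with `ratio`.
#' @export
sustained_elevation_test <- function(waveforms, delay_window = c(0.1, 2),
                                     baseline_window = c(-0.5, 0),
                                     config = perm_config()) {
  if (length(waveforms) < 2) stop("need >= 2 subjects")
  lr <- vapply(waveforms, function(w) {
    log(window_mean(w, delay_window) / window_mean(w, baseline_window))
  }, 0)
  config$tail <- "one_greater"
  res <- perm_test_signflip(lr, config)
  res$ratio <- exp(mean(lr))
  res
}

#' Peak of the M100-like response
#'
#' Finds the maximum sample within a search window after S1 onset (default
#' 70--130 ms, bracketing the expected ~100-ms peak of the major early
#' auditory evoked component) and returns its strength and latency.
#'
#' @param waveform A `source_waveform` (time 0 at S1 onset).
#' @param search `c(start, end)` search window in seconds after S1 onset.
#' @return List with `peak_strength` and `peak_latency` (s).
#' @export
m100_peak <- function(waveform, search = c(0.07, 0.13)) {
  check_window(search)
  t <- waveform_time(waveform)
  idx <- which(in_window(t, search))
  if (!length(idx)) stop("search window contains no samples")
  i <- idx[which.max(waveform$samples[idx])]
  list(peak_strength = waveform$samples[i], peak_latency = t[i])
}
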