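#' Standard analysis windows of a trial
#'
#' The three windows used throughout the spike and LFP analyses, derived from
#' the trial event times (all trials in a block share one time base):
#' `baseline` is the 500 ms directly before S1, `delay_final` the final 500 ms
#' of the delay (directly before S2 onset), and `full_delay` the interval from
#' S1 offset to S2 onset. All windows are half-open `[start, end)`.
#'
#' @param trials Trial table from [generate_block()].
#' @return Named list of `c(start, end)` windows in seconds.
#' @export
analysis_windows <- function(trials) {
  if (nrow(trials) < 1) stop("empty trial table")
  if (length(unique(trials$t_s1_on)) != 1L ||
      length(unique(trials$t_s2_on)) != 1L) {
    stop("trials must share one event-time base")
  }
  tr <- trials[1, ]
  list(
    baseline = c(tr$t_s1_on - 0.5, tr$t_s1_on),
    delay_final = c(tr$t_s2_on - 0.5, tr$t_s2_on),
    full_delay = c(tr$t_s1_off, tr$t_s2_on)
  )
}

resolve_window <- function(window, trials) {
  if (is.character(window)) {
    analysis_windows(trials)[[match.arg(window,
      c("delay_final", "baseline", "full_delay"))]]
  } else {
    check_window(window)
  }
}

#' Spike rate in a window
#'
#' Counts spikes with times in the half-open window `[start, end)` and divides
#' by the window length. A spike exactly at the window end is excluded.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param window `c(start, end)` in seconds.
#' @return Rate in spikes/s.
#' @export
spike_rate <- function(spike_times, window) {
  check_window(window)
  sum(in_window(spike_times, window)) / diff(window)
}

#' Per-trial spike rates in a window
#'
#' @param spikes Spike table (`trial_id`, `time`) from
#'   [simulate_unit_spikes()].
#' @param trials Trial table; one rate is returned per row, in order.
#' @param window Window name (`"delay_final"`, `"baseline"`, `"full_delay"`)
#'   or `c(start, end)` seconds.
#' @return Numeric vector of rates (spikes/s), aligned with `trials`.
#' @export
trial_rates <- function(spikes, trials, window = "delay_final") {
  win <- resolve_window(window, trials)
  keep <- in_window(spikes$time, win)
  counts <- table(factor(spikes$trial_id[keep], levels = trials$trial_id))
  as.numeric(counts) / diff(win)
}

filter_context <- function(trials, context) {
  if (is.null(context)) return(trials)
  out <- trials[trials$context %in% context, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no trials with context in {", paste(context, collapse = ", "),
         "}; present: ", paste(unique(trials$context), collapse = ", "),
         " (did you run simulate_behavior()?)")
  }
  out
}

# Epsilon guard for rate ratios: half of the smallest resolvable rate given
# the window length and trial count, added to both means (or to every
# per-trial rate in paired log differences) only when a mean would otherwise
# be zero. Preserves the ratio's direction; results using it are flagged.
rate_eps <- function(window_length, n_trials) {
  1 / (2 * window_length * n_trials)
}

#' High-/low-load spike-rate ratio with permutation p-value
#'
#' The ratio of the mean spike rate in high-load trials to that in low-load
#' trials within a window (by default the final 500 ms of the delay), tested
#' against 1 by a two-sample label permutation on the per-trial rates with the
#' absolute log ratio as statistic, so a ratio g and its reciprocal 1/g are
#' equally extreme. By default only correct trials enter.
#'
#' @param spikes Spike table for one unit.
#' @param trials Trial table.
#' @param window Window name or `c(start, end)`.
#' @param config A [perm_config()]; the statistic is forced to
#'   `"log_ratio_of_means"`.
#' @param context Behavioral context filter (default `"correct"`); `NULL`
#'   disables filtering.
#' @param levels Two condition labels to contrast, numerator first (default
#'   `c("high", "low")`; use `c("go", "nogo")` for task 3).
#' @return A `perm_result` augmented with `ratio`, `window`, `n_high`,
#'   `n_low`, `eps_used`.
#' @export
load_ratio <- function(spikes, trials, window = "delay_final",
                       config = perm_config(), context = "correct",
                       levels = c("high", "low")) {
  trials <- filter_context(trials, context)
  win <- resolve_window(window, trials)
  rates <- trial_rates(spikes, trials, win)
  x <- rates[trials$load == levels[1]]
  y <- rates[trials$load == levels[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 trials per condition (have ", length(x), " '", levels[1],
         "' and ", length(y), " '", levels[2], "')")
  }
  eps <- rate_eps(diff(win), length(x) + length(y))
  config$statistic <- "log_ratio_of_means"
  res <- perm_test_two_sample(x, y, config, eps = eps)
  mx <- mean(x); my <- mean(y)
  eps_used <- mx <= 0 || my <= 0
  if (eps_used) { mx <- mx + eps; my <- my + eps }
  undefined <- mean(x) == 0 && mean(y) == 0
  res$ratio <- if (undefined) NA_real_ else mx / my
  res$window <- win
  res$n_high <- length(x)
  res$n_low <- length(y)
  res$eps_used <- eps_used
  res$undefined <- undefined
  res
}

#' Delay/baseline spike-rate ratio with paired permutation p-value
#'
#' The ratio of a unit's mean rate in the final 500 ms of the delay to its
#' mean rate in the 500 ms before S1, over trials of one load. Values > 1
#' indicate delay enhancement, < 1 suppression. The p-value comes from a
#' sign-flip permutation of the per-trial log rate differences (delay vs
#' baseline within the same trial), with the epsilon guard applied to every
#' per-trial rate.
#'
#' @param spikes Spike table for one unit.
#' @param trials Trial table.
#' @param load Condition label selecting the trials (e.g. `"high"`).
#' @param config A [perm_config()].
#' @param context Behavioral context filter (default `"correct"`).
#' @return A `perm_result` augmented with `ratio`, `direction`
#'   (`"enhanced"`/`"suppressed"`/`"none"` at `alpha`), `n_trials`.
#' @param alpha Significance level used only to label the direction.
#' @export
delay_baseline_ratio <- function(spikes, trials, load = "high",
                                 config = perm_config(), context = "correct",
                                 alpha = 0.05) {
  trials <- filter_context(trials, context)
  trials <- trials[trials$load == load, , drop = FALSE]
  if (nrow(trials) < 2) stop("need >= 2 trials of load '", load, "'")
  wins <- analysis_windows(trials)
  rd <- trial_rates(spikes, trials, wins$delay_final)
  rb <- trial_rates(spikes, trials, wins$baseline)
  eps <- rate_eps(diff(wins$delay_final), nrow(trials))
  d <- log(rd + eps) - log(rb + eps)
  res <- perm_test_signflip(d, config)
  md <- mean(rd); mb <- mean(rb)
  if (md <= 0 || mb <= 0) { md <- md + eps; mb <- mb + eps }
  res$ratio <- if (mean(rd) == 0 && mean(rb) == 0) NA_real_ else md / mb
  res$direction <- if (is.na(res$ratio) || res$p_value >= alpha) "none"
                   else if (res$ratio > 1) "enhanced" else "suppressed"
  res$n_trials <- nrow(trials)
  res
}

#' Classify a unit's task/stimulus specificity
#'
#' A unit whose high-/low-load ratio is significant in exactly one of the two
#' load-reversed tasks is classed as working-memory related: late
#' stimulus-evoked activity would produce the same difference in both tasks,
#' and preparatory activity a reversed difference in both tasks, so either
#' confound yields significance in both tasks or neither.
#'
#' @param result_task1,result_task6 [load_ratio()] results for the same unit
#'   in tasks 1 and 6.
#' @param alpha Significance level.
#' @return An object of class `unit_classification` with `category`
#'   (`"task1_only"`, `"task6_only"`, `"both"`, `"neither"`), `wm_related`,
#'   and per-task `direction`.
#' @export
classify_unit <- function(result_task1, result_task6, alpha = 0.05) {
  s1 <- result_task1$p_value < alpha
  s6 <- result_task6$p_value < alpha
  category <- if (s1 && s6) "both"
              else if (s1) "task1_only"
              else if (s6) "task6_only"
              else "neither"
  dir_of <- function(res, sig) {
    if (!sig || is.na(res$ratio)) "none"
    else if (res$ratio > 1) "enhanced" else "suppressed"
  }
  structure(
    list(significant_task1 = s1, significant_task6 = s6,
         category = category, wm_related = xor(s1, s6),
         direction_task1 = dir_of(result_task1, s1),
         direction_task6 = dir_of(result_task6, s6),
         p_task1 = result_task1$p_value, p_task6 = result_task6$p_value,
         ratio_task1 = result_task1$ratio, ratio_task6 = result_task6$ratio,
         alpha = alpha),
    class = "unit_classification"
  )
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf("Unit classification: %s (%s)\n", x$category,
              if (x$wm_related) "WM-related" else "not WM-related"))
  cat(sprintf("  task 1: ratio %.3g, p = %.3g (%s)\n",
              x$ratio_task1, x$p_task1, x$direction_task1))
  cat(sprintf("  task 6: ratio %.3g, p = %.3g (%s)\n",
              x$ratio_task6, x$p_task6, x$direction_task6))
  invisible(x)
}

#' Association between task-specific load effects and best frequency
#'
#' Tests whether units with significant load ratios only in task 1 are
#' over-represented among units tuned near tone A (default band 2.67--3.37
#' kHz) and task-6-only units among units tuned near tone B (0.89--1.12 kHz),
#' each by a one-tailed chi-square on the in-band vs out-of-band proportions.
#'
#' @param categories Character vector of unit categories from
#'   [classify_unit()].
#' @param best_frequencies Numeric vector of best frequencies (kHz), aligned
#'   with `categories`.
#' @param bands Named list of inclusive frequency bands.
#' @return List of two [chisq_one_tailed()] results (`task1_only`,
#'   `task6_only`), each with `k_in`, `n_in`, `k_out`, `n_out` attached.
#' @export
bf_association <- function(categories, best_frequencies,
                           bands = list(task1_only = c(2.67, 3.37),
                                        task6_only = c(0.89, 1.12))) {
  stopifnot(length(categories) == length(best_frequencies))
  out <- list()
  for (cat_name in names(bands)) {
    band <- bands[[cat_name]]
    in_band <- best_frequencies >= band[1] & best_frequencies <= band[2]
    if (!any(in_band) || all(in_band)) {
      stop("band [", band[1], ", ", band[2], "] kHz splits no units")
    }
    k_in <- sum(categories == cat_name & in_band)
    k_out <- sum(categories == cat_name & !in_band)
    res <- chisq_one_tailed(k_in, sum(in_band), k_out, sum(!in_band),
                            direction = "first_greater")
    res$k_in <- k_in; res$n_in <- sum(in_band)
    res$k_out <- k_out; res$n_out <- sum(!in_band)
    res$band <- band
    out[[cat_name]] <- res
  }
  out
}

#' Is a unit responsive to S1?
#'
#' A unit counts as responsive when, for at least one S1 stimulus, its mean
#' rate in the 200 ms after S1 onset exceeds the mean baseline rate by at
#' least two standard errors of the baseline rate.
#'
#' @param spikes Spike table for one unit.
#' @param trials Trial table.
#' @param evoked_length Length of the post-onset window (s).
#' @return Logical.
#' @export
responsive_to_s1 <- function(spikes, trials, evoked_length = 0.2) {
  wins <- analysis_windows(trials)
  on <- trials$t_s1_on[1]
  rb <- trial_rates(spikes, trials, wins$baseline)
  se_b <- stats::sd(rb) / sqrt(length(rb))
  for (lab in unique(substr(trials$sequence, 1, 1))) {
    sel <- substr(trials$sequence, 1, 1) == lab
    re <- trial_rates(spikes, trials[sel, , drop = FALSE],
                      c(on, on + evoked_length))
    if (mean(re) >= mean(rb) + 2 * se_b) return(TRUE)
  }
  FALSE
}
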