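# Canned simulation studies of the pipeline's operating characteristics.
# These are the package's standard benchmark configurations; the acceptance
# script and the test suite run them unchanged.

#' False-positive calibration of the load-ratio permutation test
#'
#' Simulates units with identical Poisson rates in high- and low-load trials
#' (no load effect), runs the high-/low-load ratio permutation test on each,
#' and reports the fraction rejected at the criterion — which should match
#' the nominal level.
#'
#' @param n_units Number of null units.
#' @param trials_per_load Trials per load condition.
#' @param baseline_rate Poisson rate in spikes/s.
#' @param n_permutations Permutations per unit.
#' @param alpha Significance criterion.
#' @param seed Master seed.
#' @return List with `fraction_significant`, `p_values`, `n_units`.
#' @export
null_calibration_experiment <- function(n_units = 1000, trials_per_load = 100,
                                        baseline_rate = 10,
                                        n_permutations = 1000, alpha = 0.05,
                                        seed = 1) {
  task <- build_task(1, "monkey")
  trials <- generate_block(task, 2 * trials_per_load * 2, seed = seed,
                           mode = "balanced")
  trials <- simulate_behavior(trials, accuracy = 1, seed = seed + 1)
  truth <- unit_truth(baseline_rate = baseline_rate)
  p <- vapply(seq_len(n_units), function(i) {
    sp <- simulate_unit_spikes(truth, trials, seed = seed + 10 + i)
    load_ratio(sp, trials,
               config = perm_config(n_permutations,
                                    seed = seed + 500000L + i))$p_value
  }, 0)
  list(fraction_significant = mean(p < alpha), p_values = p,
       n_units = n_units, alpha = alpha)
}

#' Differential-latency recovery across two regions
#'
#' Simulates two unit populations whose high-load rate divergence starts at
#' onsets drawn uniformly from region-specific ranges (defaults mimic an
#' early sensory region at 30--70 ms and a downstream frontal region at
#' 130--170 ms after S1 offset), estimates each unit's differential latency
#' in 10-ms bins, and compares the group medians. Recovery uses a
#' two-consecutive-bin criterion, which keeps spurious single-bin hits from
#' biasing the earliest-bin estimate (see [differential_latency()]).
#'
#' @param n_per_region Units per region.
#' @param onsets_a,onsets_b Uniform onset ranges (s after S1 offset).
#' @param gain High-load delay gain.
#' @param baseline_rate Baseline rate, spikes/s.
#' @param trials_per_cond Trials per load condition.
#' @param n_permutations Permutations per unit and for the group comparison.
#' @param run_length Consecutive-bin criterion for the latency estimate.
#' @param seed Master seed.
#' @return List with `median_difference` (ms), `p_value`, `latencies_a`,
#'   `latencies_b`.
#' @export
latency_recovery_experiment <- function(n_per_region = 50,
                                        onsets_a = c(0.03, 0.07),
                                        onsets_b = c(0.13, 0.17),
                                        gain = 1.8, baseline_rate = 20,
                                        trials_per_cond = 300,
                                        n_permutations = 1000,
                                        run_length = 2, seed = 1) {
  task <- build_task(1, "monkey")
  trials <- generate_block(task, 2 * trials_per_cond * 2, seed = seed,
                           mode = "balanced")
  trials <- simulate_behavior(trials, accuracy = 1, seed = seed + 1)
  onsets <- with_seed(seed + 2, list(
    a = stats::runif(n_per_region, onsets_a[1], onsets_a[2]),
    b = stats::runif(n_per_region, onsets_b[1], onsets_b[2])
  ))
  estimate <- function(onset, i) {
    truth <- unit_truth(baseline_rate = baseline_rate,
                        delay_gain = c("1.high" = gain),
                        divergence_latency = onset)
    sp <- simulate_unit_spikes(truth, trials, seed = seed + 100 + i)
    differential_latency(sp, trials, run_length = run_length,
                         config = perm_config(n_permutations,
                                              seed = seed + 900000L + i)
                         )$latency_ms
  }
  lat_a <- vapply(seq_len(n_per_region),
                  function(i) estimate(onsets$a[i], i), 0)
  lat_b <- vapply(seq_len(n_per_region),
                  function(i) estimate(onsets$b[i], n_per_region + i), 0)
  cmp <- compare_latencies(lat_a, lat_b,
                           perm_config(2000, seed = seed + 3))
  list(median_difference = cmp$median_difference, p_value = cmp$p_value,
       latencies_a = lat_a, latencies_b = lat_b)
}

#' High-pass control study on sustained load offsets
#'
#' Plants a sustained delay offset at every site, runs the high-/low-load
#' window contrast on the raw and on the 4-Hz high-pass filtered traces, and
#' reports how many sites are detected in each. Sustained (DC-like) load
#' differences should be detected at essentially every site unfiltered and
#' fall to the false-positive level after filtering.
#'
#' Note that the filter removes low-frequency noise along with the sustained
#' offset, so a 500-ms window mean becomes ~5x less noisy while ~2.5% of the
#' offset survives as edge rebound: filtering reduces the detectability of a
#' sustained offset by roughly a factor of 8, not to exactly zero. The
#' default noise level places the unfiltered per-site effect near z ~ 5 and
#' the filtered one near z ~ 0.6.
#'
#' @param n_sites Number of sites.
#' @param offset Sustained load offset in the high condition.
#' @param noise_sd Per-sample noise SD.
#' @param trials_per_cond Trials per load condition.
#' @param n_permutations Permutations per test.
#' @param alpha Significance criterion.
#' @param seed Master seed.
#' @return List with `n_sites`, `raw_significant`, `filtered_significant`,
#'   `mean_raw_difference`, `mean_filtered_difference`.
#' @export
highpass_control_experiment <- function(n_sites = 20, offset = 5,
                                        noise_sd = 150, trials_per_cond = 100,
                                        n_permutations = 500, alpha = 0.05,
                                        seed = 1) {
  task <- build_task(1, "monkey")
  trials <- generate_block(task, 2 * trials_per_cond * 2, seed = seed,
                           mode = "balanced")
  trials <- simulate_behavior(trials, accuracy = 1, seed = seed + 1)
  raw_sig <- logical(n_sites); filt_sig <- logical(n_sites)
  raw_d <- numeric(n_sites); filt_d <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    site <- site_truth(site_id = paste0("s", i),
                       load_offset = c("1.high" = offset),
                       noise_sd = noise_sd)
    lfp <- simulate_lfp(site, trials, seed = seed + 10 + i)
    raw <- high_low_lfp_diff(lfp, trials,
                             config = perm_config(n_permutations,
                                                  seed = seed + 1000 + i))
    filt <- high_low_lfp_diff(highpass_control(lfp), trials,
                              config = perm_config(n_permutations,
                                                   seed = seed + 2000 + i))
    raw_sig[i] <- raw$p_value < alpha
    filt_sig[i] <- filt$p_value < alpha
    raw_d[i] <- raw$difference
    filt_d[i] <- filt$difference
  }
  list(n_sites = n_sites, raw_significant = sum(raw_sig),
       filtered_significant = sum(filt_sig),
       mean_raw_difference = mean(raw_d),
       mean_filtered_difference = mean(filt_d))
}
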