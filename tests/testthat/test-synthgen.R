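test_that("degenerate unit is homogeneous Poisson at the baseline rate", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 400, seed = 41)   # 400 x 2.7 s = 1080 s
  truth <- unit_truth(baseline_rate = 10)
  sp <- simulate_unit_spikes(truth, trials, seed = 42)
  total_time <- sum(trials$t_end)
  rate <- nrow(sp) / total_time
  se <- sqrt(10 / total_time)
  expect_lt(abs(rate - 10), 3 * se)
  # spikes sorted within trial and inside the trial span
  expect_true(all(sp$time >= 0 & sp$time < trials$t_end[1]))
  expect_true(all(tapply(sp$time, sp$trial_id, function(x) !is.unsorted(x))))
})

test_that("planted delay gains set the final-500-ms rate ratio", {
  for (gain in c(1.5, 0.75)) {
    pu <- planted_unit("1.high", gain, n_trials = 400, seed = 43 + gain * 10)
    wins <- analysis_windows(pu$trials)
    r <- trial_rates(pu$spikes, pu$trials, wins$delay_final)
    ratio <- mean(r[pu$trials$load == "high"]) / mean(r[pu$trials$load == "low"])
    # analytic oracle: E[high]/E[low] = gain, Poisson SE ~ 5% at these counts
    expect_equal(ratio, gain, tolerance = 0.12)
  }
})

test_that("evoked transients and context gating shape the rate", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 300, seed = 45)
  truth <- unit_truth(baseline_rate = 5,
                      evoked = list(A = c(peak = 80, decay = 0.05)))
  sp <- simulate_unit_spikes(truth, trials, seed = 46)
  on <- trials$t_s1_on[1]
  isA <- substr(trials$sequence, 1, 1) == "A"
  evoked_A <- mean(trial_rates(sp, trials[isA, ], c(on, on + 0.1)))
  evoked_B <- mean(trial_rates(sp, trials[!isA, ], c(on, on + 0.1)))
  expect_gt(evoked_A, evoked_B + 20)
  expect_true(responsive_to_s1(sp, trials))

  # gains gated on context: passive trials show no load effect
  passive <- simulate_behavior(
    generate_block(t1, 300, seed = 47, mode = "balanced",
                   context = "passive_trained"), 1, seed = 48)
  gated <- unit_truth(baseline_rate = 10, delay_gain = c("1.high" = 2))
  spp <- simulate_unit_spikes(gated, passive, seed = 49)
  res <- load_ratio(spp, passive, context = "passive_trained",
                    config = perm_config(400, seed = 50))
  expect_equal(res$ratio, 1, tolerance = 0.1)
})

test_that("window spike counts have Poisson dispersion", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 1000, seed = 51)
  sp <- simulate_unit_spikes(unit_truth(baseline_rate = 12), trials, seed = 52)
  counts <- trial_rates(sp, trials, analysis_windows(trials)$delay_final) * 0.5
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.8)
  expect_lt(fano, 1.2)
})

test_that("generators are seed-reproducible and seeds decorrelate", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 32, seed = 53)
  truth <- unit_truth(baseline_rate = 15)
  expect_identical(simulate_unit_spikes(truth, trials, seed = 9),
                   simulate_unit_spikes(truth, trials, seed = 9))
  a <- simulate_unit_spikes(truth, trials, seed = 9)
  b <- simulate_unit_spikes(truth, trials, seed = 10)
  expect_false(nrow(a) == nrow(b) && all(a$time == b$time))

  st <- site_truth(noise_sd = 5)
  expect_identical(simulate_lfp(st, trials, seed = 3)$samples,
                   simulate_lfp(st, trials, seed = 3)$samples)
})

test_that("LFP window means superpose the configured components", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 200, seed = 54)
  wins <- analysis_windows(trials)

  # pure noise: delay-window means near 0
  quiet <- simulate_lfp(site_truth(noise_sd = 5), trials, seed = 55)
  m <- window_mean(quiet, wins$delay_final)
  expect_lt(abs(mean(m)), 3 * 5 / sqrt(500) / sqrt(200))

  # load offset +5 in high only
  lo <- simulate_lfp(site_truth(load_offset = c("1.high" = 5), noise_sd = 5),
                     trials, seed = 56)
  m <- window_mean(lo, wins$delay_final)
  d <- mean(m[trials$load == "high"]) - mean(m[trials$load == "low"])
  expect_equal(d, 5, tolerance = 0.1)

  # common -8 with +3 on high: delay-baseline -5 (high) and -8 (low)
  mix <- simulate_lfp(site_truth(load_offset = c("1.high" = 3),
                                 common_offset = -8, noise_sd = 5),
                      trials, seed = 57)
  db <- window_mean(mix, wins$delay_final) - window_mean(mix, wins$baseline)
  expect_equal(mean(db[trials$load == "high"]), -5, tolerance = 0.15)
  expect_equal(mean(db[trials$load == "low"]), -8, tolerance = 0.15)
})

test_that("tuning block covers the stated grid and recovers best frequency", {
  f <- tuning_grid()
  expect_length(f, 40)
  expect_equal(f[1], 0.0625)
  expect_equal(f[40], 16)
  expect_equal(diff(log2(f)), rep(8 / 39, 39))  # log-equidistant, 8 octaves

  tb <- simulate_tuning_block(unit_truth(best_frequency = 3, tuning_width = 0.3,
                                         tuning_gain = 60), seed = 58)
  expect_equal(nrow(tb), 400)
  est <- estimate_bf(tb)
  expect_true(est$reliable)
  step <- 2^(8 / 39)
  expect_lte(abs(log2(est$best_frequency) - log2(3)), log2(step) + 1e-9)

  flat <- simulate_tuning_block(unit_truth(baseline_rate = 10, tuning_gain = 0),
                                seed = 59)
  expect_false(estimate_bf(flat)$reliable)
})

test_that("source waveforms are positive with an M100 peak and log-normal spread", {
  p <- source_params(sigma = 0)
  wf <- simulate_source_waveforms(p, 3, seed = 60)
  # sigma = 0: all subjects identical to the template
  expect_identical(wf[[1]]$samples, wf[[3]]$samples)
  expect_true(all(sapply(wf, function(w) all(w$samples > 0))))
  pk <- m100_peak(wf[[1]])
  expect_equal(pk$peak_latency, 0.1, tolerance = 1.5 / p$sampling_rate)

  wf2 <- simulate_source_waveforms(source_params(sigma = 0.2), 100, seed = 61)
  high <- wf2[sapply(wf2, function(w) w$condition) == "high"]
  at_half_s <- sapply(high, function(w) window_mean(w, c(0.5, 0.502)))
  expect_gt(stats::shapiro.test(log(at_half_s))$p.value, 0.01)
  expect_equal(stats::sd(log(at_half_s)), 0.2, tolerance = 0.3)
})
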