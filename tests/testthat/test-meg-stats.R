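split_conditions <- function(wf) {
  cond <- vapply(wf, function(w) w$condition, "")
  list(high = wf[cond == "high"], low = wf[cond == "low"])
}

test_that("baseline-offset correction subtracts the pre-S1 mean", {
  w <- structure(list(samples = rep(3.5, 2000), sampling_rate = 1000,
                      t0 = -0.5), class = "source_waveform")
  expect_true(all(abs(baseline_offset_correct(w)$samples) < 1e-12))

  set.seed(161)
  sig <- structure(list(samples = rnorm(2000), sampling_rate = 1000,
                        t0 = -0.5), class = "source_waveform")
  shifted <- sig
  shifted$samples <- sig$samples + 11
  expect_equal(baseline_offset_correct(shifted)$samples,
               baseline_offset_correct(sig)$samples)

  zero_base <- sig
  pre <- waveform_time(sig) < 0 & waveform_time(sig) >= -0.3
  zero_base$samples[pre] <- zero_base$samples[pre] - mean(zero_base$samples[pre])
  expect_equal(baseline_offset_correct(zero_base)$samples, zero_base$samples)

  late <- sig
  late$t0 <- -0.1
  expect_error(baseline_offset_correct(late), "pre-S1")
})

test_that("grand geometric mean obeys the log-average identities", {
  mk <- function(samples, id = "s") {
    structure(list(subject_id = id, condition = "high", samples = samples,
                   sampling_rate = 100, t0 = 0), class = "source_waveform")
  }
  w <- mk(c(2, 5, 9))
  expect_equal(grand_geomean(list(w, w, w))$samples, w$samples)
  gm <- grand_geomean(list(mk(c(1, 4)), mk(c(100, 4), "s2")))
  expect_equal(gm$samples, c(10, 4))  # sqrt(1*100) = 10
  # AM-GM: strict wherever subjects differ
  a <- mk(c(2, 3, 7)); b <- mk(c(5, 3, 1), "s2")
  gg <- grand_geomean(list(a, b))$samples
  am <- (a$samples + b$samples) / 2
  expect_true(all(gg <= am + 1e-12))
  expect_true(gg[1] < am[1] && gg[3] < am[3])
  expect_equal(gg[2], am[2])
  # exact identity with the arithmetic mean of logs
  expect_equal(log(gg), rowMeans(cbind(log(a$samples), log(b$samples))))

  bad <- mk(c(1, -1))
  expect_error(grand_geomean(list(bad)), "strictly positive")
})

test_that("window ratio tests find a late load effect in the right window", {
  set.seed(162)
  hits <- replicate(20, {
    wf <- simulate_source_waveforms(
      source_params(late_gain = c(high = 1.15, low = 1), sigma = 0.1), 12)
    sc <- split_conditions(wf)
    wrt <- window_ratio_test(sc$high, sc$low)
    c(final = wrt$significant[3], early = any(wrt$significant[1:2]))
  })
  expect_gte(mean(hits["final", ]), 0.7)   # target power >= 80%
  expect_lte(mean(hits["early", ]), 0.3)

  # no effect: corrected rejections stay near the corrected level
  null_hits <- replicate(30, {
    wf <- simulate_source_waveforms(
      source_params(late_gain = c(high = 1, low = 1), sigma = 0.1), 12)
    sc <- split_conditions(wf)
    any(window_ratio_test(sc$high, sc$low)$significant)
  })
  expect_lte(mean(null_hits), 0.2)
})

test_that("ratio tests are invariant to per-subject rescaling", {
  wf <- simulate_source_waveforms(
    source_params(late_gain = c(high = 1.2, low = 1), sigma = 0.1), 8,
    seed = 163)
  sc <- split_conditions(wf)
  scaled <- lapply(seq_along(sc$high), function(i) {
    w <- sc$high[[i]]; w$samples <- w$samples * (i + 1); w
  })
  scaled_low <- lapply(seq_along(sc$low), function(i) {
    w <- sc$low[[i]]; w$samples <- w$samples * (i + 1); w
  })
  expect_equal(window_ratio_test(sc$high, sc$low),
               window_ratio_test(scaled, scaled_low))
})

test_that("sustained elevation is detected one-tailed at exhaustive resolution", {
  wf <- simulate_source_waveforms(source_params(sustain_amp = 5, sigma = 0.1),
                                  12, seed = 164)
  sc <- split_conditions(wf)
  res <- sustained_elevation_test(sc$high)
  expect_true(res$exhaustive)
  expect_gt(res$ratio, 1.2)
  expect_lte(res$p_value, 0.001)           # 1/4096 attainable

  # flat template: wrong-direction tail
  flat <- simulate_source_waveforms(
    source_params(sustain_amp = -3, m100_amp = 5, sigma = 0.05), 10,
    seed = 165)
  fc <- split_conditions(flat)
  expect_gt(sustained_elevation_test(fc$high)$p_value, 0.9)
})

test_that("M100 peak is located and load-independent at the peak", {
  p <- source_params(sigma = 0)
  wf <- simulate_source_waveforms(p, 5, seed = 166)
  sc <- split_conditions(wf)
  pk_h <- m100_peak(grand_geomean(sc$high))
  pk_l <- m100_peak(grand_geomean(sc$low))
  expect_equal(pk_h$peak_latency, 0.1, tolerance = 1.5 / p$sampling_rate)
  expect_equal(pk_h$peak_strength / pk_l$peak_strength, 1, tolerance = 1e-9)

  mono <- structure(list(samples = seq(100, 1, length.out = 400),
                         sampling_rate = 1000, t0 = 0),
                    class = "source_waveform")
  expect_equal(m100_peak(mono)$peak_latency, 0.07)
  expect_error(m100_peak(mono, search = c(0.5, 0.6)), "no samples")
})
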