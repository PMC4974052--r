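test_that("spike_rate counts in half-open windows", {
  expect_equal(spike_rate(c(0.1, 0.2, 0.3, 0.35, 0.4), c(0, 0.5)), 10)
  expect_equal(spike_rate(numeric(), c(0, 0.5)), 0)
  # spike exactly at the window end is excluded, at the start included
  expect_equal(spike_rate(c(0.5), c(0, 0.5)), 0)
  expect_equal(spike_rate(c(0), c(0, 0.5)), 2)
  expect_error(spike_rate(1, c(0.5, 0.5)), "end > start")
})

test_that("analysis windows derive from the trial event times", {
  trials <- correct_block(monkey_task1(), 8, seed = 71)
  w <- analysis_windows(trials)
  expect_equal(w$baseline, c(0.5, 1.0))
  expect_equal(w$delay_final, c(1.5, 2.0))
  expect_equal(w$full_delay, c(1.2, 2.0))
})

test_that("load_ratio recovers planted gains and is reciprocal under swap", {
  pu <- planted_unit("1.high", 1.5, n_trials = 400, seed = 72)
  res <- load_ratio(pu$spikes, pu$trials, config = perm_config(1000, seed = 73))
  expect_perm_result(res)
  expect_gt(res$ratio, 1.4 - 0.03)
  expect_lt(res$ratio, 1.6 + 0.03)
  expect_lt(res$p_value, 0.05)

  # swapping the contrast inverts the ratio exactly and keeps p (equal group
  # sizes + the same permutation seed give the identical null set under |.|)
  swapped <- load_ratio(pu$spikes, pu$trials,
                        config = perm_config(1000, seed = 73),
                        levels = c("low", "high"))
  expect_equal(swapped$ratio, 1 / res$ratio)
  expect_equal(swapped$p_value, res$p_value)

  expect_error(load_ratio(pu$spikes, pu$trials[1:3, ]), ">= 2 trials")
})

test_that("silent units flag the epsilon guard instead of failing", {
  trials <- correct_block(monkey_task1(), 20, seed = 74)
  silent <- data.frame(unit_id = character(), trial_id = integer(),
                       time = numeric())
  res <- load_ratio(silent, trials, config = perm_config(100, seed = 75))
  expect_true(res$undefined)
  expect_true(is.na(res$ratio))
  expect_equal(res$p_value, 1)
})

test_that("delay/baseline ratio separates enhancement from suppression", {
  t1 <- monkey_task1()
  trials <- correct_block(t1, 300, seed = 76)

  stationary <- simulate_unit_spikes(unit_truth(baseline_rate = 10), trials,
                                     seed = 77)
  res0 <- delay_baseline_ratio(stationary, trials, "high",
                               perm_config(400, seed = 78))
  expect_equal(res0$ratio, 1, tolerance = 0.15)

  up <- simulate_unit_spikes(unit_truth(baseline_rate = 10,
                                        delay_gain = c("1.high" = 1.4)),
                             trials, seed = 79)
  res_hi <- delay_baseline_ratio(up, trials, "high", perm_config(400, seed = 80))
  res_lo <- delay_baseline_ratio(up, trials, "low", perm_config(400, seed = 81))
  expect_equal(res_hi$ratio, 1.4, tolerance = 0.15)
  expect_identical(res_hi$direction, "enhanced")
  expect_equal(res_lo$ratio, 1, tolerance = 0.15)

  down <- simulate_unit_spikes(unit_truth(baseline_rate = 10,
                                          delay_gain = c("1.high" = 0.7)),
                               trials, seed = 82)
  res_dn <- delay_baseline_ratio(down, trials, "high", perm_config(400, seed = 83))
  expect_lt(res_dn$ratio, 1)
  expect_identical(res_dn$direction, "suppressed")
})

test_that("classification follows the two-task significance pattern", {
  mk <- function(p, ratio) list(p_value = p, ratio = ratio)
  c1 <- classify_unit(mk(0.01, 1.5), mk(0.40, 1.05))
  expect_identical(c1$category, "task1_only")
  expect_true(c1$wm_related)
  expect_identical(c1$direction_task1, "enhanced")
  c2 <- classify_unit(mk(0.01, 1.5), mk(0.02, 0.8))
  expect_identical(c2$category, "both")
  expect_false(c2$wm_related)
  expect_identical(c2$direction_task6, "suppressed")
  c3 <- classify_unit(mk(0.5, 1.0), mk(0.5, 1.0))
  expect_identical(c3$category, "neither")
  expect_false(c3$wm_related)
})

test_that("with no effect anywhere P(wm_related) is about 2a(1-a)", {
  # classification needs only the two p-values; simulate them as the
  # permutation engine produces them under the null (uniform on a lattice)
  set.seed(84)
  n <- 4000
  alpha <- 0.05
  p1 <- (sample.int(1000, n, replace = TRUE)) / 1000
  p6 <- (sample.int(1000, n, replace = TRUE)) / 1000
  wm <- xor(p1 < alpha, p6 < alpha)
  expected <- 2 * alpha * (1 - alpha)
  expect_equal(mean(wm), expected, tolerance = 0.25)
})

test_that("best-frequency association uses the stated bands", {
  set.seed(85)
  n <- 120
  bf <- 2^runif(n, log2(0.0625), log2(16))
  in1 <- bf >= 2.67 & bf <= 3.37
  in6 <- bf >= 0.89 & bf <= 1.12
  # plant task-specific effects preferentially in the matching bands
  cat1 <- ifelse(in1 & runif(n) < 0.7, "task1_only",
                 ifelse(in6 & runif(n) < 0.7, "task6_only", "neither"))
  res <- bf_association(cat1, bf)
  expect_lt(res$task1_only$p_value, 0.05)
  expect_lt(res$task6_only$p_value, 0.05)
  expect_equal(res$task1_only$band, c(2.67, 3.37))
  expect_equal(res$task6_only$band, c(0.89, 1.12))

  # effects independent of tuning: no association expected
  cat0 <- sample(c("task1_only", "task6_only", "neither"), n, TRUE,
                 prob = c(0.15, 0.15, 0.7))
  res0 <- bf_association(cat0, bf)
  expect_gt(res0$task1_only$p_value, 0.01)
  expect_error(bf_association(rep("neither", 5), rep(100, 5)), "splits no units")
})
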