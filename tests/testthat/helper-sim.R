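# Builders shared across tests. Blocks are balanced so the two load
# conditions have exactly equal trial counts, and every trial is marked
# correct so the default context filter keeps all of them.

correct_block <- function(task, n_trials, seed) {
  simulate_behavior(generate_block(task, n_trials, seed = seed,
                                   mode = "balanced"),
                    accuracy = 1, seed = seed + 1)
}

monkey_task1 <- function() build_task(1, "monkey")
monkey_task6 <- function() build_task(6, "monkey")

# One unit with a single planted delay gain, simulated on a fresh block.
planted_unit <- function(gain_key, gain, n_trials = 200, baseline = 10,
                         divergence = 0, seed = 1, task = monkey_task1()) {
  trials <- correct_block(task, n_trials, seed)
  truth <- unit_truth(baseline_rate = baseline,
                      delay_gain = stats::setNames(gain, gain_key),
                      divergence_latency = divergence)
  list(trials = trials,
       spikes = simulate_unit_spikes(truth, trials, seed = seed + 2),
       truth = truth)
}

expect_perm_result <- function(res) {
  expect_s3_class(res, "perm_result")
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
}
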