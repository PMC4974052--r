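#' Ground-truth parameters of a simulated unit
#'
#' Describes the firing model of one unit (single unit or multiunit): a
#' baseline Poisson rate, stimulus-evoked onset transients, and a persistent
#' delay-period modulation that is gated by task and memory load and switches
#' on at a configurable divergence latency after S1 offset. The gain map is
#' the device by which the confound scenarios are planted: a load-gated gain
#' in one task only is working-memory-like; the same gain tied to one stimulus
#' in both tasks mimics late stimulus-evoked activity; a gain tied to the
#' go-relevant S1 in both tasks mimics preparatory activity.
#'
#' @param unit_id Unit identifier.
#' @param region `"AC"` or `"vlPFC"`.
#' @param baseline_rate Baseline rate in spikes/s (>= 0).
#' @param evoked Named list per stimulus label, each `c(peak = , decay = )`:
#'   an exponential onset transient with peak rate (spikes/s, added to
#'   baseline) decaying with the given time constant (s).
#' @param delay_gain Named numeric vector of multiplicative gains on the
#'   baseline rate during the delay, keyed `"<task>.<load>"` (e.g.
#'   `c("1.high" = 1.5)`); unlisted combinations have gain 1. All gains must
#'   be > 0.
#' @param divergence_latency Time after S1 offset (s) at which the delay gain
#'   switches on; before it the rate stays at baseline.
#' @param best_frequency Center of the unit's tuning curve in kHz.
#' @param tuning_width Tuning-curve SD in octaves (Gaussian on log2
#'   frequency).
#' @param tuning_gain Peak evoked rate (spikes/s) at the best frequency in the
#'   tuning block; 0 yields a flat, untuned unit.
#' @param context_gate Behavioral contexts in which the delay gains apply
#'   (default `"correct"`, i.e. effects are present only when the task is
#'   performed correctly); use e.g. `c("correct", "error", "passive_trained")`
#'   for ungated effects.
#' @return An object of class `unit_truth`.
#' @export
unit_truth <- function(unit_id = "u1", region = c("AC", "vlPFC"),
                       baseline_rate = 10, evoked = list(),
                       delay_gain = numeric(), divergence_latency = 0,
                       best_frequency = 3, tuning_width = 0.5,
                       tuning_gain = 20, context_gate = "correct") {
  region <- match.arg(region)
  if (baseline_rate < 0) stop("'baseline_rate' must be >= 0")
  if (length(delay_gain) && (is.null(names(delay_gain)) || any(delay_gain <= 0))) {
    stop("'delay_gain' must be a named vector of positive gains")
  }
  if (divergence_latency < 0) stop("'divergence_latency' must be >= 0")
  for (ev in evoked) {
    if (!all(c("peak", "decay") %in% names(ev)) || ev[["decay"]] <= 0) {
      stop("each 'evoked' entry needs c(peak=, decay=) with decay > 0")
    }
  }
  structure(
    list(unit_id = unit_id, region = region, baseline_rate = baseline_rate,
         evoked = evoked, delay_gain = delay_gain,
         divergence_latency = divergence_latency,
         best_frequency = best_frequency, tuning_width = tuning_width,
         tuning_gain = tuning_gain, context_gate = context_gate),
    class = "unit_truth"
  )
}

gain_for <- function(truth, task_id, load) {
  key <- paste(task_id, load, sep = ".")
  g <- truth$delay_gain[key]
  ifelse(is.na(g), 1, g)
}

# Per-candidate-spike rate evaluation for the thinning sampler. `tr` is the
# trial table row-expanded to candidate level.
unit_rate_at <- function(truth, t, tr, gain) {
  lam <- rep(truth$baseline_rate, length(t))
  t_div <- tr$t_s1_off + truth$divergence_latency
  in_gain <- t >= t_div & t < tr$t_s2_on
  lam[in_gain] <- truth$baseline_rate * gain[in_gain]
  s1 <- substr(tr$sequence, 1, 1)
  s2 <- substr(tr$sequence, 2, 2)
  for (lab in names(truth$evoked)) {
    ev <- truth$evoked[[lab]]
    hit1 <- s1 == lab & t >= tr$t_s1_on
    lam[hit1] <- lam[hit1] +
      ev[["peak"]] * exp(-(t[hit1] - tr$t_s1_on[hit1]) / ev[["decay"]])
    hit2 <- s2 == lab & t >= tr$t_s2_on
    lam[hit2] <- lam[hit2] +
      ev[["peak"]] * exp(-(t[hit2] - tr$t_s2_on[hit2]) / ev[["decay"]])
  }
  pmax(lam, 0)
}

#' Simulate spike trains for one unit across trials
#'
#' Draws independent inhomogeneous-Poisson spike trains by thinning. The rate
#' is `baseline * g(t)` plus the stimulus-evoked transients, where `g(t)` is 1
#' outside the delay and equals the unit's (task, load) gain from the
#' divergence latency after S1 offset until S2 onset. Gains are applied only
#' in trials whose behavioral context is listed in the unit's `context_gate`.
#'
#' @param truth A `unit_truth`.
#' @param trials Trial table from [generate_block()].
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `unit_id`, `trial_id`, `time` (seconds
#'   from trial start, sorted within trial).
#' @examples
#' task <- build_task(1, "monkey")
#' trials <- simulate_behavior(generate_block(task, 40, seed = 1), 1)
#' sp <- simulate_unit_spikes(unit_truth(baseline_rate = 20), trials, seed = 2)
#' @export
simulate_unit_spikes <- function(truth, trials, seed = NULL) {
  stopifnot(inherits(truth, "unit_truth"))
  n <- nrow(trials)
  gain <- ifelse(trials$context %in% truth$context_gate,
                 gain_for(truth, trials$task_id, trials$load), 1)
  peak_sum <- sum(vapply(truth$evoked, function(ev) max(ev[["peak"]], 0), 0))
  lam_max <- truth$baseline_rate * pmax(1, gain) + peak_sum
  with_seed(seed, {
    n_cand <- stats::rpois(n, lam_max * trials$t_end)
    idx <- rep.int(seq_len(n), n_cand)
    t_cand <- stats::runif(sum(n_cand)) * trials$t_end[idx]
    tr <- trials[idx, c("sequence", "t_s1_on", "t_s1_off", "t_s2_on"),
                 drop = FALSE]
    lam <- unit_rate_at(truth, t_cand, tr, gain[idx])
    keep <- stats::runif(length(t_cand)) * lam_max[idx] < lam
    out <- data.frame(unit_id = truth$unit_id,
                      trial_id = trials$trial_id[idx][keep],
                      time = t_cand[keep], stringsAsFactors = FALSE)
    out[order(match(out$trial_id, trials$trial_id), out$time), , drop = FALSE]
  })
}

#' Ground-truth parameters of a simulated LFP site
#'
#' The site model superposes stimulus-evoked transients, a load-gated
#' sustained offset during the delay, a common (load-independent) sustained
#' offset representing mental processes other than memory, and additive noise.
#' Offsets are additive because field potentials are signed; the common offset
#' lets working-memory and non-memory effects mix with opposite signs.
#'
#' @param site_id Site identifier.
#' @param evoked_amp Amplitude of the S1/S2 onset transients (arbitrary
#'   units).
#' @param evoked_decay Transient decay constant (s).
#' @param load_offset Named additive offsets during the delay keyed
#'   `"<task>.<load>"`, e.g. `c("1.high" = 5)`; unlisted combinations are 0.
#' @param common_offset Additive delay offset applied in both loads.
#' @param divergence_latency Time after S1 offset (s) at which the delay
#'   offsets switch on.
#' @param noise_sd Noise SD per sample.
#' @param noise `"white"` Gaussian or `"one_over_f"`.
#' @param context_gate Contexts in which the load offsets apply (the common
#'   offset is always applied in task contexts).
#' @return An object of class `site_truth`.
#' @export
site_truth <- function(site_id = "s1", evoked_amp = 0, evoked_decay = 0.05,
                       load_offset = numeric(), common_offset = 0,
                       divergence_latency = 0, noise_sd = 10,
                       noise = c("white", "one_over_f"),
                       context_gate = "correct") {
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(load_offset) && is.null(names(load_offset))) {
    stop("'load_offset' must be named '<task>.<load>'")
  }
  structure(
    list(site_id = site_id, evoked_amp = evoked_amp,
         evoked_decay = evoked_decay, load_offset = load_offset,
         common_offset = common_offset,
         divergence_latency = divergence_latency, noise_sd = noise_sd,
         noise = noise, context_gate = context_gate),
    class = "site_truth"
  )
}

one_over_f_noise <- function(n_trials, n_samples, sd) {
  # Spectral synthesis: amplitude ~ 1/sqrt(f), random phases, rescaled to sd.
  nf <- floor(n_samples / 2)
  f <- seq_len(nf)
  out <- matrix(0, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    amp <- stats::rnorm(nf) / sqrt(f)
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = c(0, amp, numeric(n_samples - nf - 1)),
                    argument = c(0, phase, numeric(n_samples - nf - 1)))
    x <- Re(stats::fft(spec, inverse = TRUE))
    out[i, ] <- x / stats::sd(x) * sd
  }
  out
}

#' Simulate local field potential traces for one site
#'
#' @param site A `site_truth`.
#' @param trials Trial table from [generate_block()].
#' @param seed Optional integer seed.
#' @param sampling_rate Samples per second (default 1000).
#' @return An object of class `lfp_set`: a list with `site_id`, `trial_id`,
#'   `t` (sample times, seconds from trial start), `sampling_rate`, `t0`, and
#'   `samples`, an `n_trials x n_samples` matrix.
#' @export
simulate_lfp <- function(site, trials, seed = NULL, sampling_rate = 1000) {
  stopifnot(inherits(site, "site_truth"))
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  t_end <- trials$t_end[1]
  if (any(trials$t_end != t_end)) stop("trials must share a common time base")
  t <- seq(0, t_end - 1 / sampling_rate, by = 1 / sampling_rate)
  n <- nrow(trials)
  base <- matrix(0, n, length(t))
  tr1 <- trials[1, ]
  if (site$evoked_amp != 0) {
    ev <- function(on) ifelse(t >= on,
                              site$evoked_amp * exp(-(t - on) / site$evoked_decay), 0)
    evoked <- ev(tr1$t_s1_on) + ev(tr1$t_s2_on)
    base <- base + matrix(evoked, n, length(t), byrow = TRUE)
  }
  delay_idx <- t >= tr1$t_s1_off + site$divergence_latency & t < tr1$t_s2_on
  gated <- trials$context %in% site$context_gate
  key <- paste(trials$task_id, trials$load, sep = ".")
  off <- site$load_offset[key]
  off[is.na(off)] <- 0
  off <- ifelse(gated, off, 0) + site$common_offset
  base[, delay_idx] <- base[, delay_idx] + off
  noise <- with_seed(seed, {
    if (site$noise_sd == 0) {
      matrix(0, n, length(t))
    } else if (site$noise == "white") {
      matrix(stats::rnorm(n * length(t), sd = site$noise_sd), n, length(t))
    } else {
      one_over_f_noise(n, length(t), site$noise_sd)
    }
  })
  structure(
    list(site_id = site$site_id, trial_id = trials$trial_id, t = t,
         sampling_rate = sampling_rate, t0 = 0, samples = base + noise),
    class = "lfp_set"
  )
}

#' The pure-tone frequency grid of the tuning block
#'
#' 40 log-equidistant frequencies spanning 8 octaves from 0.0625 to 16 kHz.
#'
#' @return Numeric vector of frequencies in kHz.
#' @export
tuning_grid <- function() {
  2^seq(log2(0.0625), log2(16), length.out = 40)
}

#' Simulate a best-frequency tuning block
#'
#' Presents each of the 40 grid tones (100-ms duration, 500-ms onset interval)
#' 10 times and draws Poisson spike counts from a Gaussian-on-log-frequency
#' tuning curve centered on the unit's best frequency.
#'
#' @param truth A `unit_truth`.
#' @param seed Optional integer seed.
#' @param n_reps Repetitions per tone (default 10).
#' @param count_window Length of the counting window per tone (s).
#' @return A `data.frame` with columns `frequency` (kHz), `rep`, `count`.
#' @export
simulate_tuning_block <- function(truth, seed = NULL, n_reps = 10,
                                  count_window = 0.1) {
  stopifnot(inherits(truth, "unit_truth"))
  f <- tuning_grid()
  rate <- truth$baseline_rate + truth$tuning_gain *
    exp(-((log2(f) - log2(truth$best_frequency))^2) /
          (2 * truth$tuning_width^2))
  grid <- expand.grid(frequency = f, rep = seq_len(n_reps))
  grid$count <- with_seed(seed, {
    stats::rpois(nrow(grid), rate[match(grid$frequency, f)] * count_window)
  })
  grid
}

#' Estimate a unit's best frequency from a tuning block
#'
#' The best frequency is the grid frequency maximizing the mean evoked count.
#' The estimate is flagged unreliable (untuned) unless the peak-to-mean count
#' contrast reaches `contrast_min` *and* the peak exceeds the overall mean by
#' more than Poisson counting noise allows for the best of `n_frequencies`
#' draws (a Bonferroni-style z threshold): with few repetitions the maximum
#' of 40 noisy means exceeds a fixed contrast easily, so the contrast rule
#' alone would call flat units tuned.
#'
#' @param tuning Output of [simulate_tuning_block()].
#' @param contrast_min Minimum max/mean contrast for a reliable estimate.
#' @param noise_level Family-wise probability that a flat unit passes the
#'   counting-noise criterion.
#' @return List with `best_frequency` (kHz), `reliable` (logical), and
#'   `contrast`.
#' @export
estimate_bf <- function(tuning, contrast_min = 1.2, noise_level = 0.01) {
  m <- tapply(tuning$count, tuning$frequency, mean)
  f <- as.numeric(names(m))
  n_reps <- max(tuning$rep)
  overall <- mean(m)
  z_thresh <- stats::qnorm(1 - noise_level / length(m))
  z <- if (overall > 0) (max(m) - overall) / sqrt(overall / n_reps) else 0
  list(best_frequency = f[which.max(m)],
       reliable = overall > 0 && max(m) / overall >= contrast_min &&
         z > z_thresh,
       contrast = if (overall > 0) max(m) / overall else NA_real_)
}

#' Template parameters for simulated source waveforms
#'
#' The template is a strictly positive source-strength time course: a
#' baseline, an M100-like Gaussian peak 100 ms after each tone onset, a
#' sustained elevation throughout the delay, and a late multiplicative load
#' gain in the final 500 ms of the delay. Time 0 is S1 onset; the epoch spans
#' 500 ms before S1 to 500 ms after S2 onset.
#'
#' @param baseline Baseline source strength (arbitrary units, > 0).
#' @param m100_amp Peak amplitude of the M100-like component above baseline.
#' @param m100_latency Peak latency after tone onset (s).
#' @param m100_width Gaussian SD of the peak (s).
#' @param sustain_amp Sustained elevation during the delay above baseline.
#' @param late_gain Named multiplicative gains in the final 500 ms of the
#'   delay per condition, e.g. `c(high = 1.15, low = 1)`.
#' @param sigma SD of the between-subject log-normal scaling.
#' @param sampling_rate Samples per second (default 678.17, the study-1
#'   acquisition rate).
#' @param s1_duration,soa Stimulus duration and S1-to-S2 onset interval (s).
#' @return A list of class `source_params`.
#' @export
source_params <- function(baseline = 10, m100_amp = 25, m100_latency = 0.1,
                          m100_width = 0.015, sustain_amp = 5,
                          late_gain = c(high = 1.15, low = 1), sigma = 0.1,
                          sampling_rate = 678.17, s1_duration = 0.1,
                          soa = 2.0) {
  if (baseline <= 0) stop("'baseline' must be > 0")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (is.null(names(late_gain)) || any(late_gain <= 0)) {
    stop("'late_gain' must be a named vector of positive gains")
  }
  structure(
    list(baseline = baseline, m100_amp = m100_amp,
         m100_latency = m100_latency, m100_width = m100_width,
         sustain_amp = sustain_amp, late_gain = late_gain, sigma = sigma,
         sampling_rate = sampling_rate, s1_duration = s1_duration, soa = soa,
         t0 = -0.5, t_end = soa + 0.5),
    class = "source_params"
  )
}

source_template <- function(params, condition) {
  t <- seq(params$t0, params$t_end - 1 / params$sampling_rate,
           by = 1 / params$sampling_rate)
  bump <- function(on) {
    params$m100_amp *
      exp(-((t - on - params$m100_latency)^2) / (2 * params$m100_width^2))
  }
  x <- params$baseline + bump(0) + bump(params$soa)
  delay <- t >= params$s1_duration & t < params$soa
  x[delay] <- x[delay] + params$sustain_amp
  late <- t >= params$soa - 0.5 & t < params$soa
  x[late] <- x[late] * params$late_gain[[condition]]
  list(t = t, samples = x)
}

#' Simulate per-subject source waveforms
#'
#' Each subject's waveform in each condition is the condition template scaled
#' by `exp(eps)`, `eps ~ Normal(0, sigma^2)` drawn independently per subject
#' and condition — a multiplicative (log-normal) between-subject variability
#' that keeps the waveforms strictly positive.
#'
#' @param params A `source_params`.
#' @param n_subjects Number of subjects.
#' @param seed Optional integer seed.
#' @return A list of `source_waveform` objects (one per subject per
#'   condition), each with `subject_id`, `condition`, `samples`,
#'   `sampling_rate`, `t0`.
#' @export
simulate_source_waveforms <- function(params, n_subjects, seed = NULL) {
  stopifnot(inherits(params, "source_params"))
  conditions <- names(params$late_gain)
  with_seed(seed, {
    out <- list()
    for (k in seq_len(n_subjects)) {
      for (cond in conditions) {
        tpl <- source_template(params, cond)
        eps <- stats::rnorm(1, 0, params$sigma)
        out[[length(out) + 1L]] <- structure(
          list(subject_id = paste0("sub", k), condition = cond,
               samples = tpl$samples * exp(eps),
               sampling_rate = params$sampling_rate, t0 = params$t0),
          class = "source_waveform"
        )
      }
    }
    out
  })
}

#' Sample times of a waveform or trace
#'
#' @param x A `source_waveform` or `lfp_set`.
#' @return Numeric vector of sample times in seconds.
#' @export
waveform_time <- function(x) {
  if (inherits(x, "lfp_set")) return(x$t)
  x$t0 + (seq_along(x$samples) - 1) / x$sampling_rate
}
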