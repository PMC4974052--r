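#' Auditory stimulus description
#'
#' A minimal description of one of the stimuli used in the delayed-comparison
#' tasks: pure tones (A, B, C), a white-noise burst (D), a frequency-modulated
#' tone (E), or a click train (F).
#'
#' @param label Single letter in `A`--`F`.
#' @param kind One of `"tone"`, `"noise"`, `"fm_tone"`, `"click_train"`.
#' @param frequency Tone frequency in kHz; must be given for tones and omitted
#'   (`NA`) for non-tonal stimuli.
#' @param duration Stimulus duration in seconds (> 0).
#' @param level Presentation level in dB.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(label, kind = c("tone", "noise", "fm_tone", "click_train"),
                          frequency = NA_real_, duration = 0.1, level = 70) {
  kind <- match.arg(kind)
  if (!is.character(label) || length(label) != 1L || !label %in% LETTERS[1:6]) {
    stop("'label' must be one of A-F")
  }
  if (duration <= 0) stop("'duration' must be > 0")
  if (kind == "tone" && !is.finite(frequency)) {
    stop("tones must have a frequency (kHz)")
  }
  if (kind != "tone" && is.finite(frequency)) {
    stop("non-tonal stimuli must not carry a frequency")
  }
  structure(
    list(label = label, kind = kind, frequency = frequency,
         duration = duration, level = level),
    class = "stimulus_spec"
  )
}

task_sequences <- function(task_id) {
  switch(as.character(task_id),
    "1" = , "2" = , "3" = , "6" = c("AA", "AB", "BA", "BB"),
    "4" = paste0(rep(c("A", "B", "C"), each = 3), c("A", "B", "C")),
    "5" = paste0(rep(c("A", "B", "C"), each = 3), c("D", "E", "F")),
    stop("unknown task_id: ", task_id)
  )
}

task_go_sequences <- function(task_id, sequences) {
  s1 <- substr(sequences, 1, 1)
  s2 <- substr(sequences, 2, 2)
  keep <- switch(as.character(task_id),
    "1" = , "2" = sequences == "AA",
    "3" = s1 == "A",        # delayed-response: S2 is irrelevant
    "4" = s1 == s2,         # delayed match-to-sample
    "5" = s2 == "D",        # discrimination: go iff S2 is the noise burst
    "6" = sequences == "BB"
  )
  sequences[keep]
}

task_load_rule <- function(task_id, sequences) {
  s1 <- substr(sequences, 1, 1)
  labels <- switch(as.character(task_id),
    "1" = , "2" = ifelse(s1 == "A", "high", "low"),
    # Task 3 is the delayed-response control: the within-task contrast is
    # go vs nogo (determined by S1), not memory load.
    "3" = ifelse(s1 == "A", "go", "nogo"),
    "4" = rep("high", length(sequences)),
    "5" = rep("low", length(sequences)),
    "6" = ifelse(s1 == "B", "high", "low")
  )
  stats::setNames(labels, sequences)
}

task_stimuli <- function(task_id, species_profile, duration) {
  tone <- function(lab, f) stimulus_spec(lab, "tone", f, duration = duration)
  if (species_profile == "monkey") {
    return(list(A = tone("A", 3), B = tone("B", 1)))
  }
  switch(as.character(task_id),
    "1" = , "2" = , "3" = , "6" = list(A = tone("A", 1.5), B = tone("B", 1.6)),
    "4" = list(A = tone("A", 1.5), B = tone("B", 0.789), C = tone("C", 2.85)),
    "5" = list(
      A = tone("A", 1.5), B = tone("B", 0.789), C = tone("C", 2.85),
      D = stimulus_spec("D", "noise", duration = duration),
      E = stimulus_spec("E", "fm_tone", duration = duration),
      F = stimulus_spec("F", "click_train", duration = duration)
    )
  )
}

#' Build one of the six go/nogo task designs
#'
#' Constructs the full specification of one of the delayed-comparison task
#' designs: the stimulus sequences, the go rule, the per-sequence memory-load
#' labels, event timing, and the per-sequence sampling probabilities used when
#' scheduling trials. Tasks 1/2 require a go response to AA with load high when
#' S1 = A; task 6 reverses the loads (go to BB, high when S1 = B); task 3 is a
#' delayed-response control labelled go/nogo by S1; task 4 (match-to-sample) is
#' all high load and task 5 (sound discrimination) all low load.
#'
#' @param task_id Integer 1--6.
#' @param species_profile `"monkey"` (200-ms tones, SOA 1.0 or 1.3 s, biased
#'   sequence sampling) or `"human"` (100-ms tones, SOA 2.0 s, balanced
#'   blocks). Tasks 4 and 5 exist only for the human profile.
#' @param soa Stimulus-onset asynchrony S1 onset to S2 onset in seconds;
#'   defaults to the profile's standard value (monkey 1.0, human 2.0). The
#'   delay is `soa - s1_duration` and must be positive.
#' @param lead_time S1 onset relative to trial start in seconds; the default
#'   1.0 s guarantees a 500-ms pre-S1 baseline window.
#' @return An object of class `task_spec` with fields `task_id`,
#'   `species_profile`, `sequences`, `go_sequences`, `load_rule`, `soa`,
#'   `s1_duration`, `s2_duration`, `delay`, `response_window`,
#'   `sequence_probabilities`, `stimuli`, `lead_time`.
#' @examples
#' t1 <- build_task(1, "monkey")
#' t1$delay                      # 0.8 s
#' label_load(t1, "AB")          # "high"
#' @export
build_task <- function(task_id, species_profile = c("monkey", "human"),
                       soa = NULL, lead_time = 1.0) {
  species_profile <- match.arg(species_profile)
  if (length(task_id) != 1L || !task_id %in% 1:6) {
    stop("unknown task_id: ", paste(task_id, collapse = ","))
  }
  task_id <- as.integer(task_id)
  if (task_id %in% 4:5 && species_profile == "monkey") {
    stop("tasks 4 and 5 are defined for the human profile only")
  }
  dur <- if (species_profile == "monkey") 0.2 else 0.1
  if (is.null(soa)) soa <- if (species_profile == "monkey") 1.0 else 2.0
  delay <- soa - dur
  if (delay <= 0) stop("delay = soa - s1_duration must be > 0")
  if (lead_time < 0.5) stop("'lead_time' must leave room for a 500-ms baseline")

  sequences <- task_sequences(task_id)
  go_seq <- task_go_sequences(task_id, sequences)
  load_rule <- task_load_rule(task_id, sequences)
  response_window <- if (species_profile == "monkey") 1.36
                     else if (task_id %in% 4:5) 1.5 else 2.0

  # Monkey blocks present the go sequence on ~60% of trials, the remaining
  # sequences equiprobably; human blocks are balanced.
  if (species_profile == "monkey") {
    p <- stats::setNames(rep(0.4 / (length(sequences) - length(go_seq)),
                             length(sequences)), sequences)
    p[go_seq] <- 0.6 / length(go_seq)
  } else {
    p <- stats::setNames(rep(1 / length(sequences), length(sequences)), sequences)
  }

  structure(
    list(task_id = task_id, species_profile = species_profile,
         sequences = sequences, go_sequences = go_seq, load_rule = load_rule,
         soa = soa, s1_duration = dur, s2_duration = dur, delay = delay,
         response_window = response_window, sequence_probabilities = p,
         stimuli = task_stimuli(task_id, species_profile, dur),
         lead_time = lead_time),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("Task %d (%s profile)\n", x$task_id, x$species_profile))
  cat(sprintf("  sequences: %s\n", paste(x$sequences, collapse = " ")))
  cat(sprintf("  go: %s\n", paste(x$go_sequences, collapse = " ")))
  cat(sprintf("  load: %s\n",
              paste(sprintf("%s=%s", names(x$load_rule), x$load_rule),
                    collapse = " ")))
  cat(sprintf("  SOA %.3g s, S1 %.3g s, delay %.3g s\n",
              x$soa, x$s1_duration, x$delay))
  invisible(x)
}

#' Memory-load label of a sequence under a task design
#'
#' @param task A `task_spec`.
#' @param sequence Sequence string, e.g. `"AB"`.
#' @return `"high"` or `"low"` (for task 3, the contrast labels
#'   `"go"`/`"nogo"`).
#' @export
label_load <- function(task, sequence) {
  stopifnot(inherits(task, "task_spec"))
  if (!sequence %in% task$sequences) {
    stop("sequence '", sequence, "' is not part of task ", task$task_id)
  }
  unname(task$load_rule[[sequence]])
}

#' Generate a block of trials for a task
#'
#' Produces a trial table with per-trial sequence, load label, required
#' response and event times. Human-profile blocks are balanced (exactly
#' `n_trials / n_sequences` trials per sequence in shuffled order); monkey
#' blocks draw the go sequence with probability 0.6 and the remaining
#' sequences equiprobably. Passive blocks use the same schedules but carry a
#' passive context and no behavioral outcome.
#'
#' @param task A `task_spec`.
#' @param n_trials Number of trials (> 0); balanced mode requires
#'   divisibility by the number of sequences.
#' @param seed Optional integer seed.
#' @param mode `"auto"` (profile default), `"balanced"`, or `"biased"`.
#' @param context `"active"` for behaving blocks (outcomes assigned later by
#'   [simulate_behavior()]), or one of the passive contexts.
#' @return A `data.frame` with columns `trial_id`, `task_id`, `sequence`,
#'   `load`, `required_response`, `t_s1_on`, `t_s1_off`, `t_s2_on`,
#'   `t_s2_off`, `t_end`, `outcome`, `context`. All times are seconds from
#'   trial start; windows derived from them are half-open `[start, end)`.
#' @examples
#' blk <- generate_block(build_task(1, "human"), 240)
#' table(blk$sequence)  # 60 trials of each sequence
#' @export
generate_block <- function(task, n_trials, seed = NULL,
                           mode = c("auto", "balanced", "biased"),
                           context = c("active", "passive_trained",
                                       "passive_untrained")) {
  stopifnot(inherits(task, "task_spec"))
  mode <- match.arg(mode)
  context <- match.arg(context)
  if (n_trials <= 0) stop("'n_trials' must be > 0")
  if (mode == "auto") {
    mode <- if (task$species_profile == "monkey") "biased" else "balanced"
  }
  seqs <- with_seed(seed, {
    if (mode == "balanced") {
      k <- length(task$sequences)
      if (n_trials %% k != 0) {
        stop("balanced blocks need 'n_trials' divisible by ", k)
      }
      sample(rep(task$sequences, n_trials / k))
    } else {
      sample(task$sequences, n_trials, replace = TRUE,
             prob = task$sequence_probabilities)
    }
  })
  t_s1_on <- task$lead_time
  t_s1_off <- t_s1_on + task$s1_duration
  t_s2_on <- t_s1_on + task$soa
  t_s2_off <- t_s2_on + task$s2_duration
  data.frame(
    trial_id = seq_len(n_trials),
    task_id = task$task_id,
    sequence = seqs,
    load = unname(task$load_rule[seqs]),
    required_response = ifelse(seqs %in% task$go_sequences, "go", "nogo"),
    t_s1_on = t_s1_on, t_s1_off = t_s1_off,
    t_s2_on = t_s2_on, t_s2_off = t_s2_off,
    t_end = t_s2_off + 0.5,
    outcome = "none",
    context = context,
    stringsAsFactors = FALSE
  )
}

#' Default per-sequence behavioral accuracies
#'
#' Trained subjects respond correctly well above the 65% per-sequence
#' criterion; go sequences are typically easier than nogo sequences for
#' monkeys. These defaults define the standard simulated conditions: monkey go
#' sequence 0.90 and nogo sequences 0.80; human 0.90 (four-sequence tasks) or
#' 0.95 (nine-sequence tasks).
#'
#' @param task A `task_spec`.
#' @return Named numeric vector of accuracies per sequence.
#' @export
default_accuracy <- function(task) {
  stopifnot(inherits(task, "task_spec"))
  if (task$species_profile == "monkey") {
    acc <- stats::setNames(rep(0.8, length(task$sequences)), task$sequences)
    acc[task$go_sequences] <- 0.9
  } else {
    level <- if (task$task_id %in% 4:5) 0.95 else 0.9
    acc <- stats::setNames(rep(level, length(task$sequences)), task$sequences)
  }
  acc
}

#' Assign behavioral outcomes to trials
#'
#' Each active trial is independently labelled `correct` with its sequence's
#' accuracy and `error` otherwise; the `context` column is updated to match so
#' analyses can filter on behavioral context. Passive trials keep outcome
#' `none`.
#'
#' @param trials Trial table from [generate_block()].
#' @param accuracy Named per-sequence accuracies in `[0, 1]`, or a single
#'   number applied to every sequence; `NULL` uses [default_accuracy()] for
#'   the block's task (inferred from the trial table's task id and sequences).
#' @param task Optional `task_spec` used to resolve default accuracies.
#' @param seed Optional integer seed.
#' @return The trial table with `outcome` and `context` filled in.
#' @export
simulate_behavior <- function(trials, accuracy = NULL, task = NULL, seed = NULL) {
  seqs <- unique(trials$sequence)
  if (is.null(accuracy)) {
    if (is.null(task)) {
      profile <- if (all(trials$t_s1_off - trials$t_s1_on > 0.15)) "monkey" else "human"
      task <- build_task(trials$task_id[1], profile,
                         soa = trials$t_s2_on[1] - trials$t_s1_on[1])
    }
    accuracy <- default_accuracy(task)
  }
  if (is.null(names(accuracy))) {
    if (length(accuracy) != 1L) stop("unnamed 'accuracy' must be a single number")
    accuracy <- stats::setNames(rep(accuracy, length(seqs)), seqs)
  }
  missing <- setdiff(seqs, names(accuracy))
  if (length(missing)) {
    stop("missing accuracy for sequence(s): ", paste(missing, collapse = ", "))
  }
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]")
  active <- trials$context == "active"
  p <- unname(accuracy[trials$sequence])
  hit <- with_seed(seed, stats::runif(nrow(trials)) < p)
  trials$outcome[active] <- ifelse(hit[active], "correct", "error")
  trials$context[active] <- trials$outcome[active]
  trials
}
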