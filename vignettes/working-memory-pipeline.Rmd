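---
title: "Detecting working-memory-related persistent activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting working-memory-related persistent activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpersist)
```

## The scientific problem

A neuron (or field-potential site, or cortical source) that stays elevated or
suppressed during the silent delay of a delayed-comparison trial is not
necessarily storing anything. Its persistent activity could be (i) *late
activity* — a stimulus-evoked response that merely outlasts the first sound,
(ii) *preparatory activity* tied to the upcoming motor response, or (iii) any
number of slow task-general processes (attention, reward expectation). The
design this package implements separates genuine working-memory (WM) storage
from these confounds by having the same subject perform **two go/nogo tasks
with reversed memory loads on identical stimuli**:

* In task 1 a go response is required for the sequence AA; holding
  information during the delay is only necessary when S1 = A, so trials
  starting with A are *high load* and trials starting with B *low load*.
* Task 6 requires go for BB: the same physical stimuli, but the load labels
  are swapped.

A load effect caused by late activity of one stimulus would appear
identically in both tasks; a preparatory effect would follow the go-relevant
stimulus and hence also appear in both tasks (with reversed sign). Only a
genuine load effect — gated by what must be *stored* — appears in **exactly
one** of the two tasks. That exclusive-or is the classifier implemented by
`classify_unit()`, and the package's simulation suite verifies that planted
late-activity and preparatory effects are classed `both` while planted
load-gated effects are classed one-task-only.

Three further designs are covered: a delayed-response control (task 3, go
determined by S1 alone, contrasted as go vs nogo), and a
delayed-match-to-sample vs sound-discrimination pair (tasks 4 and 5, all-high
vs all-low load across nine sequences), used for the human evoked-field
analyses.

## Statistics

All hypothesis tests are permutation tests; parametric assumptions enter
nowhere in the inferential path.

**Load ratio.** For a window $w$ (by default the final 500 ms of the delay,
chosen to minimize contamination by late activity) the statistic is
$R = \bar r_{\text{high}} / \bar r_{\text{low}}$, the ratio of mean per-trial
spike rates. The permutation test shuffles load labels and uses $|\log R|$ so
that a ratio $g$ and its reciprocal $1/g$ are equally extreme — enhancement
and suppression are treated symmetrically. Monte-Carlo p-values use the
add-one rule $p = (1 + \#\{|T^*| \ge |T|\})/(B+1)$, so $p = 0$ cannot occur;
when the number of distinct label assignments is at most $10^4$ the test
enumerates them exhaustively instead. Because the permutation null depends
only on the pooled values, the engine canonicalizes the pool before drawing,
which makes the label-swap symmetry ($R \mapsto 1/R$ with identical $p$)
exact for balanced designs at a fixed seed.

**Zero-rate guard.** A silent group would make the log ratio undefined. When
either group's mean rate is zero, $\varepsilon = 1/(2\,|w|\,n)$ spikes/s —
half the smallest resolvable rate for window length $|w|$ and $n$ trials —
is added to *both* means. This preserves the direction of the ratio; results
that used the guard are flagged, and a unit silent in both groups reports an
undefined ratio with $p = 1$.

**Paired contrasts.** Delay-vs-baseline comparisons within the same trials
(`delay_baseline_ratio()`, `delay_baseline_lfp_diff()`, and all per-subject
MEG tests) use sign-flip permutations of the paired differences, enumerated
exhaustively up to $n = 13$ ($2^{13}$ flips).

**Proportions.** Population contrasts (correct vs error vs passive contexts;
800- vs 1100-ms delays) use the Pearson 2×2 chi-square without continuity
correction, one-tailed by halving the two-tailed p when the observed
direction matches the hypothesis (p = 0.5 at exactly equal proportions). The
correct-vs-error contrast can involve the same units; the result carries an
`independent` flag rather than pretending otherwise.

**Number of permutations.** The default is 2000 (1000 in the heavy batch
experiments); this is a Monte-Carlo resolution choice, not a scientific one,
and every result records the count and seed used.

## The synthetic-data generators

No recordings are distributed with this package; every analysis is exercised
on synthetic data whose ground truth is known, which is what turns the test
suite into a parameter-recovery and calibration study.

**Spikes.** Each unit is an inhomogeneous Poisson process sampled by
thinning: rate $\lambda(t) = b\,g(t) + \sum_s A_s e^{-(t-t_s)/\tau_s}$, with
baseline $b$, exponential onset transients at the stimulus times (default
decay 50 ms — onset responses are visible in cortical recordings but their
shape is not critical to any analysis here), and a delay gain $g(t)$ that
equals a task- and load-specific multiplier from a configurable *divergence
latency* after S1 offset until S2 onset, and 1 elsewhere. Gains are
multiplicative so rates stay non-negative; they are gated on the behavioral
context (default: present in correct trials only), which is how
context-dependence experiments are planted. The confound scenarios are
expressed through the gain map alone: `c("1.high" = g, "6.low" = g)` is a
late-activity unit (effect tied to stimulus A in both tasks),
`c("1.high" = g, "6.high" = g)` a preparatory unit, `c("1.high" = g)` a
stimulus-specific WM unit. Where a magnitude distribution is needed the
session simulator draws gains uniformly from 0.75–1.9, the range of observed
load ratios; this is a modeling choice, not an empirical distribution.

**LFP.** Sites superpose signed additive components: evoked transients, a
load-gated sustained delay offset, a *common* sustained offset applied in
both loads (mental processes other than WM), and white Gaussian noise
(1/f noise is available; the true noise spectrum is not constrained by the
data the design rests on). The superposition is what produces the
characteristic pattern in which both loads change relative to baseline but
the low-load trials change more — a WM offset of +3 on a common offset of −8
yields delay−baseline differences of −5 (high) and −8 (low).

**Tuning blocks.** Best frequency is assessed from 40 log-equidistant tones
spanning 0.0625–16 kHz (8 octaves), 10 repetitions each, counted over the
100-ms tone; expected counts follow a Gaussian tuning curve on log
frequency. The estimator is the argmax of mean counts. A pure
max/mean-contrast criterion (≥ 1.2) cannot distinguish flat units from tuned
ones at these counts — the maximum of 40 Poisson means exceeds 1.2× the
grand mean by chance almost always — so reliability additionally requires
the peak to exceed the grand mean by more than a Bonferroni-style Poisson
counting-noise threshold (family-wise 1%).

**Source waveforms.** The human evoked-field stage synthesizes strictly
positive source-strength time courses: baseline, an M100-like Gaussian peak
100 ms after each tone onset, a sustained delay elevation, and a late
multiplicative load gain in the final 500 ms. Subject $k$'s waveform is the
template times $e^{\varepsilon_k}$, $\varepsilon_k \sim N(0, \sigma^2)$
drawn per subject and condition — multiplicative between-subject
variability, which is exactly the situation in which the **geometric** mean
(`grand_geomean()`: exponentiated pointwise mean of logs) is the right
grand average and log ratios are the right per-subject statistics. All ratio
tests are therefore invariant to per-subject rescaling, which the suite
checks exactly. Baseline-offset correction (subtracting the 300-ms pre-S1
mean) is provided for signed sensor-like inputs but never applied to the
positive source strengths. The sampling rate defaults to 678.17 Hz, the
acquisition rate of the four-sequence human study.

## Windows, time bases, numerical conventions

* Time 0 is trial start; S1 onset sits at a 1-s lead time so a 500-ms
  pre-S1 baseline always exists. Source waveforms use S1 onset as time 0.
* Every window is half-open $[t_0, t_1)$: a spike exactly at the window end
  is excluded, one at the start included.
* Standard windows: baseline = 500 ms before S1; final delay window =
  500 ms before S2 onset; full delay = S1 offset to S2 onset. The three
  500-ms MEG delay windows partition the delay backward from S2 onset; their
  exact placement within the 1.9-s delay is a configuration knob
  (`delay_window_set()`), since only their count and width are pinned down
  by the design.
* Permutation tie comparisons use a relative tolerance of $10^{-8}$ so that
  floating-point jitter cannot flip an exhaustive count.
* The Bonferroni factor for the MEG window tests is the number of windows
  (3); an argument extends it if hemispheres are to be folded in.
* The M100 search window is 70–130 ms after tone onset, bracketing the
  component's nominal latency.

## Differential latency and the run-length choice

`differential_latency()` tests consecutive 10-ms bins spanning the delay
(grid anchored at S1 offset; a final partial bin is dropped with a warning)
with two-sample permutation tests on per-trial bin rates, and reports the
start time of the earliest significant bin. All bins share one set of label
permutations — each bin's marginal null is unchanged, and the per-unit cost
becomes a single matrix product.

The literal single-bin criterion is the default (`run_length = 1`), but it
deserves a warning that the package's own null test quantifies: with ~80
bins at $\alpha = 0.05$, the probability that *some* null bin fires is
$1-(1-\alpha)^{80} \approx 0.98$, and a divergence preceded by $k$ null bins
is pre-empted by a spurious earlier bin with probability
$\approx 1-(1-\alpha)^k$. An earliest-bin estimator built on it is therefore
biased toward zero, and the bias grows with the true latency — it would
systematically compress the very between-region difference the analysis is
meant to measure. Recovery experiments in this package
(`latency_recovery_experiment()`) therefore require two consecutive
significant bins, which cuts the spurious-run rate to
$\approx (k-1)\alpha^2 < 4\%$ while leaving a step divergence's estimate at
the same bin. Group comparisons use the difference of medians with a
two-sample permutation test; units without an estimate are excluded.

## Benchmark configurations

The canned experiments fix the package's standard operating-characteristic
studies (sizes chosen as a compromise between Monte-Carlo resolution and a
test suite that runs in minutes):

* `null_calibration_experiment()`: 1000 units, 10 spikes/s, 100 trials per
  load, 1000 permutations — the fraction significant at $p < 0.05$ should
  be 0.05.
* `latency_recovery_experiment()`: 50 units per region, onsets uniform on
  30–70 ms vs 130–170 ms after S1 offset, gain 1.8 on a 20-spikes/s
  baseline, 300 trials per condition — the median latency difference should
  recover ~100 ms. The baseline is a typical multiunit rate; it puts
  per-bin power near 1 so the estimate resolves at the bin width.
* `highpass_control_experiment()`: 20 sites with a sustained +5 load offset
  on noise of SD 150, 100 trials per condition. The 4-Hz zero-phase
  Butterworth (order 4, applied forward and backward) removes the offset's
  window-mean signal ~40-fold while removing the window-mean noise ~5-fold,
  so detection falls from every site to the false-positive level. The noise
  scale was derived from those two measured factors so that the unfiltered
  contrast sits at $z \approx 5$ and the filtered one at $z \approx 0.6$.

Behavioral defaults: monkey blocks draw the go sequence with probability
0.6 and the three nogo sequences equiprobably (the design fixes only the
60/40 go/nogo split; equiprobable nogo is the package's choice); accuracies
default to 0.90 for go and 0.80 for nogo sequences (monkey) and 0.90/0.95
(human four-/nine-sequence studies) — all comfortably above the 65%
per-sequence training criterion. Task 2 is modeled as task 1: the ear and
response hand differ, which no analysis in scope consumes. Response times
are not modeled; outcomes are Bernoulli draws per sequence.

## What passing tests do and do not show

The generators emulate the *statistical structure* the analyses assume:
Poisson spiking with multiplicative delay gains, additive LFP components,
log-normal subject variability. Real recordings violate all of these in
ways the suite cannot probe — non-Poisson dispersion, rate drift across a
session, correlated noise across trials and sites, oscillatory delay
activity (explicitly out of scope), electrode instabilities, and
eye/heartbeat artifacts that the human pipeline removes upstream of this
package's entry point. Passing the suite shows that the statistics are
calibrated and the estimators recover planted effects *under the stated
model*; it does not validate the model itself against tissue. The
between-task comparison (same S1, different task) is implemented by the
same two-sample engine but its real-data counts are not reproduction
targets, and no attempt is made to reproduce the empirical prevalence
figures of any real dataset — those depend on recordings that are not
distributed.

## Known limitations

* The divergence of high- and low-load rates is a step; real divergences
  are ramps, for which "latency" is itself fuzzy. A ramp option would make
  the recovery experiments ill-posed, so the step is the default and only
  tested shape.
* The epsilon guard biases log ratios of very sparse units toward 1;
  flagged results should be interpreted accordingly.
* Exhaustive two-sample enumeration is capped at $10^4$ assignments;
  between that and Monte-Carlo there is no branch-and-bound middle ground.
* The chi-square context contrast on overlapping unit sets is approximate
  by construction (flagged, as discussed above).
* `wm_cli()` writes wide-TSV trace containers; they are exact but not
  compact, and a binary exchange format is deliberately out of scope.
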