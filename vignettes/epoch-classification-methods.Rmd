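---
title: "Methods: peri-event epoch classification of calcium event traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event epoch classification of calcium event traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

One-photon miniscope imaging of striatal medium spiny neurons during a
self-initiated operant task produces two asynchronous data streams: a
cells-by-frames matrix of deconvolved calcium event amplitudes sampled at
20 Hz on the imaging clock, and a behavioral event log (port entries, cue
lights, reward deliveries) time-stamped on the behavioral controller's
clock. The scientific question is which neurons change their activity in
which part of the trial: before the animal initiates, while it responds to
the cue, while it waits through an imposed delay, during reward
consumption, and after. `miniepoch` implements that analysis end to end,
together with a synthetic-session generator that carries ground truth, so
every stage is testable without animal data.

# Trial structure and epochs

Two task variants are supported. In the **cue-guided** task a trial becomes
available after a variable intertrial interval (ITI, mean 45 s by default),
the animal self-initiates with a center poke, one side cue lights
immediately, and a response within a short window (1.5 s default) at the
cued port is rewarded; the non-cued port is an error; no response is an
omission. The **delay** task interposes a fixed 3 s delay between
initiation and cue onset; side pokes during the delay are counted as
premature responses but never change the trial outcome.

For correct trials, activity is evaluated in named epochs, all half-open
intervals on the behavioral clock:

| Epoch | Window |
|-------|--------|
| T | 2 s preceding trial initiation |
| C | initiation (cue onset in the delay task) through the cue response |
| D | the 3 s delay (delay task only) |
| R | 0–3 s after reward delivery |
| P | 3–6 s after reward delivery |
| baseline | last 6 s of the preceding ITI, ending at trial availability |

The cue-guided task therefore tests four epochs \{T, C, R, P\} and the delay
task five. The composition of the five-epoch set deserves a note: T, D, R
and P are unambiguous, and we retain C (cue onset to response) as the fifth
epoch because the post-delay cue response remains a distinct behavioral
event; `task_epochs(task, include_cue_in_delay = FALSE)` switches to the
four-epoch variant.

The C epoch has variable length (the response latency, about 0.9 s on
average under the defaults). All activity measures are per-second rates, so
latency differences do not bias comparisons across trials.

Because T is anchored to initiation and the baseline to availability, a
fast initiation (< 2 s after availability) lets T overlap the tail of the
baseline window. We permit the overlap — the anchors are defined
independently — and the session builders keep ITIs long enough that it is
rare; analyses needing strict exclusion can filter trials on
`initiation_time - availability_time >= 2`.

# Event rate

The deconvolved trace assigns each frame a non-negative event amplitude.
We define the **calcium event rate** in a window as the number of
supra-threshold frames per second (`threshold = 0` by default, so any
nonzero amplitude counts as an event frame). This makes the rate a pure
count statistic, robust to amplitude scale, and is the default everywhere;
`event_rate()` exposes the threshold for amplitude-weighted variants
computed by the caller. Windows are converted to frames with a floor
convention (frame *i* covers `[i/20, (i+1)/20)` seconds) and the rate
divides by the realized frame count, not the nominal window length, so
clipping at frame boundaries never biases the rate.

# Clock synchronization

Both acquisition systems record a shared train of 5 s on/off sync pulses.
`fit_clock_map()` matches edges by rank order (sliding the shorter train
along the longer when counts differ — pulse period is 10 s, far larger than
any plausible offset) and fits the affine map `imaging = offset + drift ×
behavior` by least squares. An affine rather than offset-only model is used
because independent acquisition clocks drift measurably over a 40 min
session; the pure shift is the `drift = 1` special case and is recovered
exactly on noiseless input. The fit refuses to proceed when the residual
RMS exceeds 25 ms (half a frame) or the drift leaves (0.9, 1.1), both signs
of a desynchronized or mis-paired recording.

# The permutation test

For each cell and epoch we form per-trial paired differences
`d_i = rate(epoch, trial i) − rate(baseline, trial i)` over correct trials
and test `H0: no modulation` with a two-tailed paired sign-flip permutation
test: the statistic is the mean difference, and the null distribution is
generated by flipping the sign of each `d_i` independently. We chose the
mean-difference statistic because, for paired data, sign-flipping the
differences and swapping epoch/baseline labels within a trial generate the
same null distribution for it, making the two natural permutation schemes
coincide. A studentized statistic would change only the ordering of tied
configurations and is deliberately not the default.

Numerical conventions, all visible in `paired_permutation_test()`:

* **Exact enumeration** over all `2^n` sign assignments is selected
  automatically whenever `2^n ≤ n_perm`, removing Monte-Carlo noise at
  small trial counts. The enumerated p needs no finite-sampling correction
  (the identity assignment is included, so `p ≥ 2^-n`).
* **Monte-Carlo** sampling uses the add-one estimate
  `p = (1 + #extreme) / (1 + n_perm)`, which keeps the test valid at any
  finite number of rounds (10,000 by default).
* **Ties** (`|stat_perm| = |stat_obs|`) count toward the tail —
  conservative — and the comparison uses a relative tolerance so that
  rescaling all differences by a positive constant provably leaves the
  p-value unchanged.
* Per-trial pairing with the trial's **own preceding-ITI baseline** is the
  default. Pairing each trial against the cell's across-ITI average baseline
  is a defensible alternative reading of "average baseline activity", so
  `build_rate_table(..., baseline_pairing = "session_mean")` provides it;
  the default preserves the pairing structure the test exploits.

## Familywise control and categories

p-values are thresholded at `alpha / (2 × n_epochs)` — Bonferroni across
epochs and across the two directions of change (excitation/inhibition).
For the four-epoch cue-guided task this is the `0.05/8` rule; for the
five-epoch delay task the same formula gives `0.05/10`. We generalize the
divisor with the epoch count rather than fixing 8, and
`bonferroni_threshold()` makes the choice explicit and overridable.

A cell significant in at least one epoch is *responsive* and receives a
category string listing its significant epochs with directions in the
fixed order T, C, D, R, P — e.g. `"C+R+P+"` (excited through response and
reward) or `"R-P-"` (inhibited after reward). The direction is the sign of
the observed mean difference; the test itself stays two-tailed, with the
direction split absorbed in the Bonferroni divisor.

# Population summaries

* **Proportions.** Per epoch and group, cells are counted as excited,
  inhibited or nonresponsive, and groups are compared with a Pearson
  chi-square test without continuity correction (the correction is
  available via a flag but is not the default, as the cell counts involved
  are large). Both "of all cells" and "of responsive cells" denominators
  are emitted, since both are in common use and they answer different
  questions.
* **Normalized traces.** Each cell's peri-event rate trace (averaged over
  correct trials at native 20 Hz bins) is z-scored against the mean and SD
  of that cell's per-trial baseline rates, then averaged within group with
  a SEM over cells. Cells with zero baseline SD cannot be z-scored and are
  excluded with a logged count.
* **Group × time ANOVA.** The z traces are compared with a classical
  mixed-design ANOVA (between factor: group; within factor: time bin;
  repeated-measures unit: cell), fit via `aov` with an `Error(cell)`
  stratum. Animal-level nesting is intentionally not modeled here — the
  traces are averaged per cell, and cells are the exchangeable unit in this
  summary.
* **Category tables.** `category_frequencies()` ranks categories among
  responsive cells and reports the minimal set reaching a coverage target
  (0.80 by default).
* **Correlations.** `pearson_r()` is a thin, validated wrapper around the
  two-tailed Pearson test for per-animal metrics.

# The synthetic-session generator

`generate_session()` emulates exactly the statistical structure the
analysis assumes and nothing more:

* **Event trains.** Per-frame event counts are Poisson with rate
  `baseline_rate × multiplier(epoch at that frame) / 20`. Poisson is the
  minimal model consistent with analysing an event *rate*; deconvolved data
  from real sensors is over-dispersed and temporally correlated, which this
  generator deliberately does not reproduce — passing tests certify the
  statistics under the stated model, not sensor physics.
* **Amplitudes.** Per-event amplitudes are gamma (shape 2) with mean
  `amplitude_scale`; per-frame amplitudes are the sum over that frame's
  events. The amplitude law is a modeling convenience — the default
  analysis thresholds at zero, so only event presence matters.
* **Trials.** ITIs are uniform on `iti_mean × [0.5, 1.5]` (a simple
  reading of "variable ITI"); initiation latencies are exponential (mean
  2 s); response latencies are gamma with mean 0.93 s and SD 0.3 s,
  truncated to the response window by inverse-CDF sampling; outcomes are
  drawn i.i.d. from the cohort mixture, 59% correct / 5% incorrect / 36%
  omitted by default; premature pokes in the delay task form a homogeneous
  Poisson process (0.2 pokes/s default) and never alter the outcome.
* **Clocks.** Sync edges every 5 s on the behavioral clock are mapped to
  the imaging clock through a configurable affine model (offset, drift)
  with optional Gaussian per-edge jitter — the recovery target for
  `fit_clock_map()`.
* **Cohorts.** `generate_cohort()` assigns each cell a category drawn from
  the group's mixture and converts it to epoch multipliers (excited 5.0,
  inhibited 0.1 by default — strong effects appropriate for ground-truth
  recovery checks). Per-mouse seeds derive deterministically from the group
  seed, so cohorts are reproducible cell-for-cell.
* **Motion fixtures.** `generate_motion_frames()` builds 8-bit frame
  stacks in which a square blob moves by known displacements over
  sub-threshold noise, so the pixel-change motion index has an exactly
  computable expected value.

# Locomotion index

`motion_index()` counts, per consecutive frame pair, pixels whose absolute
gray-level change strictly exceeds 10 units (strict inequality: a change
of exactly 10 is "baseline fluctuation"). Consecutive-frame differencing is
used rather than differencing against a reference frame. The 30 Hz video
counts are then converted to 20 bins/s on the imaging clock by
duration-weighted allocation — each source interval's count is split across
overlapping imaging bins in proportion to temporal overlap — which
conserves the total count exactly by construction.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed, and composite drivers
derive per-stage/per-cell seeds with `derive_seed()` (a 31-bit multiplicative
hash), so results are independent of evaluation order. Re-running any
generator or the full `run_pipeline()` with the same configuration is
bit-identical.

The shipped test-scale study conditions use a 12 s mean ITI (uniform
0.6–1.4×) instead of the behaviorally realistic 45 s: the ITI length only
needs to exceed the 6 s baseline window plus scheduling slack, and shorter
ITIs pack more trials into fewer frames. Validity is checked on 2,000 null
cells × 30 correct trials; category recovery on 500 cells × 40 trials;
the delay-period group contrast on 50 replicate cohorts of 2 × 300 cells.
These sizes give binomial standard errors small enough that each check is
discriminating (for example ±1.5 percentage points at 3 SE on a 5% false
positive rate).

# Known limitations

* The generator's Poisson event trains have no temporal autocorrelation,
  bursting, or amplitude–rate coupling; conclusions about real deconvolved
  data rest on the permutation test's validity under exchangeability, not
  on this generator.
* The mixed-design ANOVA treats cells as independent; animals are not a
  modeled level of nesting.
* Incorrect and omitted trials are excluded from classification by design;
  the package performs no inference on them.
* The upstream imaging pipeline (motion correction, source extraction,
  deconvolution) is out of scope: inputs are assumed to be valid
  non-negative event-amplitude traces.
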