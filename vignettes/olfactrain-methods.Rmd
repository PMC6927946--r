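---
title: "Models and methods behind olfactrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olfactrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactrain)
```

`olfactrain` reimplements the computational core of an automated,
RFID-gated go/no-go olfactory training system for group-housed mice, and
pairs it with a virtual rig so the whole pipeline — sequencing, trial
control, curriculum, logging, analysis — can be exercised and tested
without hardware or animals. This vignette documents the models, the
tunable parameters, the numerical decisions and their limits.

## The trial state machine

A port entry (IR beam break) becomes a trial only when a complete RFID
read identifies a registered animal; an incomplete or absent read returns
the controller to baseline and logs an `ABORTED` entry with no ITI and no
curriculum credit. An initiated trial proceeds through:

1. **Pre-sampling** (500 ms): the fraction of 1 kHz beam-state samples
   with the head in the port must reach the phase threshold before the
   final valve opens. We operationalize the "sampling rate" as this
   dimensionless fraction of occupied time — thresholds are configured as
   fractions (0–0.875), so a fraction-of-time reading is the only
   interpretation that needs no extra unit. A failed gate aborts the trial
   with no penalty: penalizing a failed gate would conflate motivation
   with discrimination performance.
2. **Stimulus** (max 2000 ms): an odor in discrimination, clean air in
   pre-training. Odor-on time is cut short by head retraction.
3. **Response**: the 2000 ms window is partitioned into four 500 ms
   blocks; a block counts if at least one lick contact falls in it. The
   phase lick criterion *k* requires ≥ *k* counting blocks; in
   discrimination a minimum of one block defines a lick response even when
   the configured criterion is 0.
4. **Outcome and ITI**: S+ with a response is a Hit (water reward), S+
   without is a Miss, S− with a response a False Alarm, S− without a
   Correct Rejection. Misses and False Alarms add the 3 s penalty to the
   1 s base ITI (4 s total); correct outcomes incur the base ITI only.

Time is integer milliseconds throughout the state machine; wall-clock
timestamps appear only at the log boundary (ISO-8601 with milliseconds).

## The staged curriculum

Pre-training shapes compliance across seven phases before any odor is
presented. The packaged defaults:

```{r}
default_curriculum()
```

Fields printed as ranges ramp linearly from start to end over the phase's
minimal trial count and clamp thereafter; no schedule beyond the endpoints
is specified by the protocol, and a linear ramp is the least-structured
interpolation. An animal advances when it has completed at least the
phase's minimal trials **and** at least 16 of its last 20 completed trials
were correct (80%). In pre-training — where there is no S− and thus no
discrimination — "correct" can only mean task compliance, so a completed
trial that ends in reward collection counts as correct; aborted entries
and failed gates are excluded from the window entirely rather than counted
against the animal. Phases never demote, matching a protocol in which an
animal simply remains in a stage until it meets the criterion. A flawless
performer therefore completes pre-training in exactly 600 completed trials
(50 + 50 + 5 × 100).

Rewarded pre-training completions are logged as `HIT` and unrewarded ones
as `MISS` so that a single invariant — positive reward volume exactly on
`HIT` rows — holds across the entire log.

Two points the protocol leaves open are resolved as configuration rather
than behavior: whether failed gates should feed the 20-trial window
(they do not, see above), and whether a post-regression minimum-trials
recheck exists (it does not; the two gates above are the whole rule).

## Constrained sequencing

Discrimination labels come in blocks of 1000 trials with exactly 50 S+ in
every consecutive 100-trial bin and no more than three consecutive
identical labels. "Approximately 50" is implemented as exactly 50: it is
the strictest reading, it makes the invariant testable, and it guarantees
an unbiased reward base rate. Runs are evaluated across bin boundaries
within a block (the run cap has no per-bin qualifier), but not across
block boundaries — each block validates standalone.

Generation is a randomized sequential construction: at each position the
admissible labels are those with remaining quota in the bin, a run not
exceeding the cap, and a completable remainder — two-symbol sequences with
counts *a*, *b* and run cap *k* are completable iff each class fits into
the gaps left by the other (*a* ≤ *k*(*b*+1), adjusted for the entry run).
The exact look-ahead means the sampler never paints itself into a corner
within a bin; bins are nonetheless retried under a bounded attempt budget
(10,000) to absorb rare boundary interactions, and exhausting it raises a
configuration error rather than silently relaxing a constraint. Choices
between two admissible labels are weighted by remaining counts, which
keeps the sampler close to a uniform draw over admissible completions
without the cost of counting them.

Each animal consumes its own independently generated blocks through a
per-animal cursor; a fresh block is issued only when the current one is
fully consumed, so no part of a sequence repeats early. Per-animal blocks
(rather than one shared block) avoid cross-animal stimulus correlation;
the choice is configurable in principle but per-animal is the default and
the tested path. All randomness flows from one seed; per-animal,
per-block sub-streams are derived deterministically from it, and the seed
is recorded in the event-log header.

Odor–reward counterbalancing splits every treatment group as evenly as
possible between the two odors (difference ≤ 1 for odd sizes, the extra
side seed-determined), so intrinsic odor preferences cannot masquerade as
treatment effects.

## The virtual rig

**Learning model.** Each agent licks on a trial with probability
`p_hit(n) = h_inf − (h_inf − h0)·exp(−n/τ)` on S+ and
`p_fa(n) = f_inf + (f0 − f_inf)·exp(−n/τ)` on S−, where *n* counts
completed discrimination trials — learning is indexed by trials, not wall
time, matching how training curves are reported in this field. Defaults
(`h0 = f0 = 0.85`, `h_inf = 0.99`, `f_inf = 0.02`, `τ = 120`) describe an
animal that leaves pre-training licking for everything and mostly stops
licking for S− within a few hundred trials, which places the 0.95
fraction-correct criterion near 300–400 trials — the range typical for a
first odor pair on such rigs. A licking response draws enough licked
blocks to meet the criterion; a non-licking S− response draws an early
head retraction uniform on 250–1200 ms.

**Initiations.** Trial initiations follow an inhomogeneous Poisson
process with piecewise-constant hourly rates. The default profile is a
circular exponential-cosine bump peaking at 21:00 (the fourth hour of an
18:00–06:00 dark phase) with concentration κ = 3 and ~300 initiations per
day, putting ~17% of daily trials in the peak hour — a strongly nocturnal
animal. Port contention is resolved by mutual exclusion: a blocked
initiation is re-tried once after an exponential delay (mean 60 s) and
dropped if the port is still busy, which reproduces the direction (not the
magnitude) of the mild per-animal trial-count decrease in larger cohorts.

**Failure modes.** Each entry fails its RFID read with probability
`p_rfid_fail` (default 0.05) and, where the gate threshold is positive,
fails pre-sampling with probability `p_presample_fail` (default 0.05).

**Olfactometer.** Pulses rise as a saturating exponential from shortly
after final-valve opening, peak at the valve's time-to-peak, and decay
slowly; amplitude is `gain × dilution` plus additive Gaussian noise
(multiplicative noise is out of scope). Defaults: onset latency 15.91 ms;
six valves with peak times spanning 65.38–91.38 ms (growing with distance
from the final valve); rise time constant one third of the onset-to-peak
interval; noise SD 0.02 at unit gain. The rise origin is placed so that
the 10%-of-maximum crossing of a noise-free trace — the onset definition
used by the pulse metrics — lands on the configured latency; the residual
calibration error from the finite peak is far below one 1 ms sample.

## Analytics

* **Windowed metrics** use a 100-trial sliding window by default. The
  window is a documented parameter recorded in outputs, not a protocol
  fact; 100 matches the bin granularity used elsewhere in the task
  design. Metrics are defined only where the window is full, and missing
  values propagate explicitly — nothing is zero-filled.
* **d′** is `qnorm(H) − qnorm(F)` with each rate clamped to
  `[1/(2N), 1 − 1/(2N)]` for its own response class, keeping perfect
  performance finite (e.g. 100/0/0/100 gives 2·Φ⁻¹(0.995) ≈ 5.15). The
  implementation is checked against an independent bisection inversion of
  the normal CDF to 1e−9.
* **Trials-to-criterion** is the index of the first completed trial whose
  window reaches the threshold (0.95 fraction correct, d′ ≥ 3); aborted
  entries never count.
* **Circadian profiles** average per-day hourly fractions over days with
  any trials; the day boundary is calendar midnight of log-local time and
  the dark phase is annotated as 18:00–06:00. Hourly performance pools
  completed trials per hour across animals.
* **Group-size effects** are plain Pearson correlations with a
  least-squares slope; zero variance in either variable is reported as an
  undefined correlation with a warning, not as 0.
* **Pulse onset** is the first 10%-of-max crossing after time zero with
  linear interpolation between samples; for an ideal step sampled at
  interval Δt the interpolated crossing lies within Δt of the step time.

## What the simulation shows — and what it cannot

The virtual rig makes the control logic testable: balance and run
constraints over arbitrary seeds, exact curriculum progression (50 trials
to leave phase 1, 600 to finish pre-training for a flawless performer),
ITI structure, outcome partitions, reward conservation, mutual exclusion,
parameter recovery of τ within 20% from 2000-trial logs, and dilution
linearity of synthetic pulses (Pearson r > 0.99 at default noise). None of
this validates animal biology: real mice carry session-to-session
motivation drift, satiety, inter-individual variability and sniff-by-sniff
sampling dynamics that the exponential-learning agent deliberately lacks.
Real-cohort outcomes (trials-to-criterion distributions, group-size effect
magnitudes) are emergent properties of animals and are not calibration
targets of this package; the rig reproduces their direction and structure,
not their numbers.

## Numerical choices and problem sizes

Determinism: every stochastic component takes a seed; generation restores
the caller's RNG state, and per-animal/per-block sub-streams are derived
arithmetically from the master seed (kept below 2³¹). Identical config and
seed reproduce a log bit-for-bit.

Event logs are RFC-4180 CSV with `#`-prefixed header lines (format
version, config hash, seed, start time); enumerations are uppercase
tokens and timestamps ISO-8601 with milliseconds, which round-trip
bit-stably. Readers reject unknown major versions and report malformed
rows by line and field.

The test suite and the acceptance script run cohort simulations at desk
scale — single animals to a handful, hours to a few simulated days,
~2000-trial logs for parameter recovery, 100 seeds for the sequencing
property — sizes chosen so the full pipeline is exercised end to end in
well under a minute per scenario on one core.

## Known limitations

* The agent model is memoryless beyond *n*: no satiety, no session
  structure, no odor-specific biases.
* Port-contention magnitude is not calibrated; only its direction is
  meaningful.
* The discrimination reward delay is fixed at the response-window end
  (2000 ms post final valve), the value shared by the late pre-training
  phases.
* Pulse shapes are phenomenological (saturating exponential), not a fluid
  dynamics model of the manifold.
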