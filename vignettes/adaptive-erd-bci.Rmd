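---
title: "Simulating auto-calibrating adaptive ERD brain-computer interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating auto-calibrating adaptive ERD brain-computer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbci)
```

## The problem

Event-related desynchronization (ERD) BCIs decode which mental task a user
is performing from task-locked decreases (or increases, ERS) of band-limited
EEG power. For users with severe motor impairment, two practical obstacles
dominate: calibration time (supervised recordings before the system works)
and the fact that classical motor-imagery (SMR) BCIs fail for a substantial
minority of users. Adaptive, auto-calibrating designs address the first
problem by calibrating on the fly from cue-labelled trials and recalibrating
as data accumulate. This package additionally models a configuration that
addresses the second: during initial auto-calibration the system screens
*four* mental tasks (two motor, two non-motor) and locks onto the binary
task pair that separates best for this user.

`adbci` implements the full simulation pipeline — montage and bipolar
derivations, trial-based outlier rejection, causal log band-power features,
LDA calibration with leave-one-out training-window search, automatic
class-pair selection, a prequential online-simulation engine, channel/class
ranking sweeps, and exact binomial chance bounds — together with a seeded
generator of synthetic ERD sessions so every stage is testable without
patient recordings.

## The decoding model

The decoder consumes one or three **bipolar derivations** (differences of
two electrodes on a common sagittal or coronal grid line, at most one grid
position skipped). Per derivation, five **log band-power features** are
computed causally: a 4th-order Butterworth band-pass (8–10, 10–13, 13–16,
16–24, 24–30 Hz), squaring, a trailing 1 s moving average, and a natural
log. The first second of each trial is warm-up and carries no feature
values. The trailing (past-only) average and causal filter are deliberate:
an online system can only use the past, so the simulation must too.

Calibration, given artifact-free trials of two classes:

1. Per derivation, keep the band with the highest **Fisher score**
   $(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2+\varepsilon)$ of the trial-mean
   feature over seconds 4–8 ($\varepsilon = 10^{-12}$; ties go to the lower
   band).
2. Split seconds 4–8 into eight adjacent 0.5 s windows. For each window,
   leave-one-out: train an LDA on the window-averaged features of the
   held-in trials, apply it to the held-out trial's full feature time
   course, pool per-timepoint correctness across folds, and take the median
   over seconds 4–8.
3. The window with the highest median accuracy (earliest on ties) trains
   the final LDA on all trials.

The LDA is the classical pooled-covariance discriminant; the pooled
covariance gets a ridge of $10^{-6}\,\mathrm{tr}(S)/p$ on its diagonal
because leave-one-out folds with seven trials per class are close to
singular. The decision boundary sits at the midpoint of the class means.

**Automatic class-pair selection** (the "Auto" configuration) runs this
calibration for all six binary combinations of the four candidate tasks and
keeps the pair with the highest LooCV median accuracy; exact ties fall back
to the Fisher score of the best selected feature, then to lexicographic
order. The pair is chosen once, at initial calibration, and kept for the
rest of the session.

## The online simulation

`runSession()` processes trials strictly in arrival order (prequentially):

* each arriving in-scope trial is screened by the outlier pipeline, with
  statistics computed over the trials collected so far;
* once every in-scope class has 7 artifact-free trials, the initial
  calibration runs (with pair selection in auto mode);
* afterwards every artifact-free trial is classified at every valid
  timepoint with the most recent model, and the system recalibrates on all
  collected trials whenever every in-scope class has 7 new artifact-free
  trials (a total-count trigger is available via `updateRule = "total"`).

The model applied to trial $i$ was trained only on trials that arrived
before $i$; results are bit-for-bit reproducible because the engine itself
draws no random numbers. Trials consumed before the initial calibration are
never retro-scored; performance is summarized by the per-timepoint accuracy
over evaluated trials, its median over seconds 4–8 (used for ranking and
model selection) and its peak in the same window (the headline measure),
with an exact binomial chance bound (`chanceLevel(60, 2, 0.01)` = 66.7%).

## Outlier rejection

Three phases, in order, separately for the relax segment (0–3 s, classes
pooled) and the imagery segment (3–8 s, per class):

1. **Amplitude**: any sample beyond ±100 μV on a screened electrode rejects
   the trial. The bound is strict (a sample at exactly 100 μV is kept).
2. **Kurtosis / probability**: per channel, each trial's sample kurtosis
   and mean log empirical density (histogram over the pooled samples, 100
   bins, lightly kernel-smoothed) are z-scored across trials; |z| > 3.5 on
   any channel rejects. With fewer than three trials, or zero across-trial
   spread, nothing is rejected.
3. **Iterative band power**: per (derivation, band), each trial's mean log
   band power is z-scored across the surviving set; trials beyond 3.5 SD
   are removed and the statistics recomputed until a pass removes nothing
   (capped at 20 iterations as a non-convergence guard).

Rejection only flags trials; signals are never modified. In the engine the
same statistics are recomputed over the trials collected so far at each
arrival, and only the arriving trial's flag is decided — past decisions are
final, as they would be online. For that prequential path the probability
histogram uses fixed bin edges spanning ±(amplitude limit), which is the
support left after the amplitude phase; this lets per-trial bin counts be
precomputed without changing what the measure estimates.

## The synthetic session generator

`generateSession()` emulates a cue-guided five-task paradigm: 8 runs × 25
trials (5 per class, randomly ordered within run), 10 s trials (relax 0–3 s,
cue at 3 s, imagery to 10 s), 30 electrodes on an integer 10/20-style grid,
256 Hz. Each channel is a sum of:

* **aperiodic background**: $1/f$-shaped Gaussian noise, band-limited to
  the 0.5–100 Hz acquisition pass band, with a spectral knee at 2 Hz
  (aperiodic EEG spectra follow $1/f$ only above a low-frequency knee; an
  unbroken $1/f$ concentrates power in a handful of ultra-slow components
  and makes short-window power estimates unrealistically heavy-tailed),
  5 μV SD;
* **white sensor noise**, 5 μV SD — active-electrode recordings in clinical
  settings carry appreciable broadband instrumentation/EMG noise, and this
  component controls the sampling behaviour of the kurtosis statistic;
* per band, an **amplitude-modulated narrowband Gaussian carrier**
  (synthesized in the frequency domain; band-limited noise rather than a
  sinusoid, so band-power estimates have realistic variance). During
  imagery the carrier amplitude is scaled by $\sqrt{1 + e}$ — band power
  changes by the fraction $e$ from the class × electrode × band effect
  matrix — with a 250 ms raised-cosine ramp at cue onset to avoid spectral
  splatter.

Artifact trials (an exact, configurable fraction at random positions)
receive five high-amplitude Gaussian-envelope spikes across all channels
(jittered per-channel gains), with one spike guaranteed in each screened
segment; they violate the ±100 μV rule by construction. Clean trials stay
below ~50 μV. Everything is reproducible from a single seed, and
`makeCohort()` derives multi-subject variants by lognormal jitter of the
effect magnitudes.

### The default effect template

The default template makes **(Hand, Word)** the designed-best pair and
places every effect on electrodes covered by the packaged default
derivations (FCz-CPz, P1-P2, CP4-PO4 for the Auto configuration; C3-CP3,
FCz-CPz, CP4-P4 for SMR), since the decoder only sees derivation signals:
hand imagery desynchronizes vertex/left-central mu (10–13 Hz, −45%/−35%),
word generation desynchronizes parietal beta (16–24 Hz, −45%) — and each of
the two modulates the *other* region in the opposite direction (ERS, +45%),
so the Hand-vs-Word contrast is roughly twice either task's contrast
against the remaining tasks. Feet, Math and Nav carry small effects (−20%
to −8%). Magnitudes were chosen so the best single-trial feature of the
designed pair has a Fisher score near 1 under the default noise; this
yields clean-session peak accuracies around 0.95 for the Auto configuration
and 0.75–0.86 for the SMR pair, and makes pair selection at seven trials
per class reliable. One-sided templates (only ERD) were found to make all
(X, Word) pairs statistically indistinguishable at that calibration size —
with 14 trials the LooCV median accuracy is quantized in steps of 1/14, so
a designed margin must be large to survive it.

### What the generator does not emulate

Trials are statistically independent given the class: there is no vigilance
drift, no session-scale nonstationarity, no eye or muscle artifact
waveforms (spikes only), no volume conduction (channels carry independent
carriers, so a bipolar derivation sums rather than cancels rhythm power),
and no co-adaptive user learning. Passing tests on this substrate
demonstrates that the decoding and adaptation machinery is correct and
well-calibrated, not that the specific accuracy numbers transfer to patient
EEG.

## Numerical choices and degenerate inputs

* Averaged band power is floored at $10^{-10}$ μV² before the log, so
  silent fixtures stay finite.
* Zero across-trial spread disables a rejection measure rather than
  dividing by zero; classes with fewer than three surviving trials skip the
  statistical phases (logged).
* All tie-breaks are deterministic: lowest band, earliest window, highest
  Fisher then lexicographic pair, lexicographic channel/class ranking.
* Half-open time windows `[start, end)` everywhere; trial time 0 is the
  relax-period start.
* Deferred calibration (a class below two artifact-free trials) is a
  signalled condition, not a crash; a stream that ends before initial
  calibration yields a result flagged "never calibrated".

## Problem sizes used in the checks

The packaged acceptance checks simulate full 200-trial sessions: 20 seeded
sessions (plus label-shuffled controls) for designed-pair recovery, a
9-subject cohort for the Auto-vs-SMR comparison, and 4 sessions at 12%
artifact injection for the rejection corridor. Unit tests run on reduced
fixtures (64 Hz, two or four electrodes, 10–40 trials) chosen so each
property is exercised in seconds.

## Known limitations

* The channel/class ranking sweep is exhaustive over derivation × pair
  cells; sweeping all 75 default-montage derivations against all 10 class
  pairs means 750 engine runs and is meant for batch use, not interactive
  sessions.
* The probability measure's estimator (histogram bins, smoothing) follows
  common EEGLAB-style practice but is not a calibrated density estimate;
  it is used only as a relative outlier score.
* Feature selection happens once per calibration, before the leave-one-out
  loop, so the LooCV accuracy is mildly optimistic — deliberately so, since
  it mirrors the procedure it simulates rather than an unbiased estimator.
* In auto mode the class pair is frozen at initial calibration; a user
  whose best pair changes mid-session would keep the initial pair.
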