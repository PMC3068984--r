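---
title: "Methods: sleep-EEG architecture and spectral statistics for stress-reactivity mouse lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-EEG architecture and spectral statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsleep)
```

## The analysis problem

Mouse lines selectively bred for high (HR), intermediate (IR) and low (LR)
corticosterone stress reactivity differ in their sleep-wake architecture
and in the spectral composition of their sleep EEG. `srsleep` implements
the full analysis chain used for this kind of study: two-channel (EEG +
EMG) recordings sampled at 64 Hz over 23 Zeitgeber hours (ZT0--ZT23,
lights off at ZT12) are cut into 4-second epochs; each epoch gets spectral
band powers and an EMG root mean square; epochs are scored as WAKE, NREMS
or REMS; the resulting hypnograms are summarised as event-history
quantities (normed state durations, normed transition frequencies, REMS
episode lengths) over four canonical intervals (L1 = ZT0--6, L2 = ZT6--12,
D1 = ZT12--18, D2 = ZT18--23); and group differences are tested with an
interval-wise MANOVA battery, one-way ANOVAs, Bonferroni-modified LSD
contrasts, and a nonparametric *stability* test that asks whether one
line's curve lies continuously above another's across the day.

Because the recordings such analyses are developed on are not generally
distributable, the package carries a first-class synthetic cohort
generator whose presets encode the qualitative line differences, so every
stage can be exercised and validated signal-to-statistics without any
data download.

## The synthetic cohort generator

### Vigilance-state dynamics

Hypnograms are sampled from a first-order Markov chain on the 4-second
epoch grid, *piecewise-homogeneous by light phase*: one 3x3 row-stochastic
transition matrix governs the light phase (epoch start before ZT12), a
second one the dark phase. The initial state is drawn from the stationary
distribution of the light matrix. A first-order chain is the simplest
structure that reproduces phase-level contrasts between the intervals
L1--D2, which is the resolution at which the downstream statistics
operate; ultradian and homeostatic (Process-S) dynamics are deliberately
not modelled.

The shipped presets differ in two places only:

* **HR** has an elevated per-epoch NREMS-to-REMS transition probability
  (0.016 light / 0.008 dark, vs 0.010 / 0.005 for IR and 0.009 / 0.0045
  for LR). Because the REMS *exit* probabilities are identical across
  lines, this raises REMS time and the NREMS->REMS and REMS->WAKE
  transition counts while leaving the REMS episode-length distribution
  unchanged -- more episodes, not longer ones.
* **LR** has depressed theta (0.12 vs 0.16) and alpha (0.09 vs 0.12)
  relative power during NREMS.

Under these presets the stationary state fractions are realistic for
nocturnal mice: light phase roughly 45% WAKE / 42--48% NREMS / 8--12%
REMS (REMS highest in HR), dark phase roughly 75% WAKE. Mean bout
lengths are about 100 s (WAKE, light), 70--90 s (NREMS) and 70 s (REMS).
These values were fixed once, from the physiology the generator is meant
to emulate, and are not tuned against any test.

### Signal synthesis

EEG epochs are built by inverse DFT of amplitude targets with independent
uniform random phases: on the 0.25 Hz bin grid of a 256-point FFT, each
band's bins receive the state's target band fraction (spread uniformly
over the band), the three inter-band gap bins receive the remainder, and
the epoch is scaled so its RMS equals the state's EEG amplitude (WAKE
40, NREMS 80, REMS 50 microvolts). This gives *exact* control of band
fractions per epoch with no filter design. Two jitter layers make the
data statistically honest rather than deterministic:

* a per-epoch lognormal perturbation of the band fractions
  (`spectral_jitter`, default sd 0.15), renormalised so the state's total
  in-band fraction is preserved -- epoch-to-epoch spectral variability;
* a per-animal lognormal perturbation of band fractions, EMG levels and
  EEG amplitude (`animal_cv`, default 0.08) -- between-animal biological
  variability, which is what gives the MANOVA/AUC statistics genuine
  within-group variance.

The EMG channel is white noise with state-dependent standard deviation
(WAKE 30, NREMS 10, REMS 2 microvolts), respecting the atonia ordering
REMS < NREMS < WAKE that the preset constructor enforces.

What the generator does *not* emulate: movement and electrode artifacts,
1/f background structure, spindles/phasic events, state-transition
ambiguity, and drift of electrode impedance. Passing round-trip tests on
this generator therefore validates the pipeline's internal consistency
and its statistical calibration, not scorer performance on real
recordings.

## Spectral features

The analog front end of the emulated recording chain is a 0.5--29 Hz
band-pass with 48 dB/octave roll-off; it is reproduced digitally as an
order-4 Butterworth applied forward and backward (`signal::filtfilt`),
i.e. zero-phase, which is the right choice when only power is analysed.
The EMG is never filtered.

Per 4-second epoch an untapered periodogram is computed on the 0.25 Hz
grid (the epoch is long relative to the band widths, and no taper is part
of the emulated processing chain; the scheme is configurable). Bands are
delta 0.75--5, theta 6--9, alpha 10--15, eta 16--22.75 and beta
23--31.75 Hz -- the eta band is a mouse-specific slice of the
conventional beta range. Band membership is *inclusive* of both edges,
which are exact grid points; the gap bins at 5.25--5.75, 9.25--9.75 and
15.25--15.75 Hz belong to the total power (0.75--31.75 Hz) but to no
band, so relative powers sum to slightly less than 1. DC and bins below
0.75 Hz are excluded everywhere. Whether a total-power denominator should
include the gap bins is a genuine convention choice; the inclusive total
is used here and is visible in `band_scheme()`. Epochs with zero total
power get `NA` relative powers and an explicit `rel_defined = FALSE`
flag rather than silent NaN propagation.

Parseval holds exactly by construction: the sum of all non-DC periodogram
bins equals the biased epoch variance (tested to 1e-8 relative).

## Vigilance scoring

Published semi-automatic scorers for this preparation are described only
by their feature space (band fractions, EMG RMS); the package therefore
implements a transparent threshold cascade over exactly that feature
space, with every threshold in configuration:

1. EMG RMS above the wake cutoff: WAKE;
2. else theta/delta ratio > 1.5 and EMG below the sleep cutoff: REMS;
3. else relative delta > 0.35: NREMS;
4. else inherit the previous epoch's state (first epoch: WAKE).

EMG cutoffs are calibrated per recording as quantiles (0.60 / 0.40) of
the epoch EMG RMS distribution -- the stand-in for an experimenter's
manual tuning; absolute cutoffs can be supplied instead. The fall-back
rule makes scoring total and deterministic; raising the wake cutoff can
never increase the number of WAKE epochs (tested as a property). No
smoothing is applied by default; a width-3 majority filter is available
(`majority_filter()`) but off, since minimum-bout post-processing is not
part of the emulated chain. Interactive rescoring is represented by a
file-based override interface (`apply_overrides()`), which marks epochs
with provenance `OVERRIDE`.

On default presets the cascade recovers the generating hypnogram on about
96% of epochs; the dominant error mode is wake epochs whose EMG falls
just below the calibrated cutoff at bout onsets, which then inherit the
preceding sleep state.

## Event-history metrics: conventions

Several boundary conventions are under-determined and had to be fixed:

* Epochs belong to the interval containing their *start* time; intervals
  are half-open, so the four intervals partition ZT0--23 without double
  counting. D2 is 5 h (ZT18--23) as recordings stop at ZT23; normed
  quantities keep intervals comparable despite unequal lengths.
* A transition is attributed to the interval (or ZT hour) of the *later*
  epoch. Splitting the recording into L1..D2 then conserves total
  transition counts exactly (tested).
* A REMS episode is a maximal run of REMS epochs, assigned to the
  interval of its first epoch and never split; its length is 4 s times
  the run length. The mean episode length of an interval without
  episodes is undefined (`NA`), not zero.
* The two recording days are *averaged* per animal (normed metrics and
  mean episode lengths with equal weight; transition counts summed and
  renormalised) rather than concatenated, making the animal the
  statistical unit.
* Hour bins are labelled by their end: hour `h` covers ZT `[h-1, h)`,
  giving the ZT1..ZT23 grid on which the stability test pairs groups.

## The statistical battery

For each interval separately, group effects are tested with a one-way
MANOVA: Wilks' lambda from the between/within SSCP matrices and Rao's F
approximation (for 5 responses, 3 groups and 23 animals this yields the
familiar F with (10, 32) degrees of freedom). A significant omnibus test
gates univariate follow-up F tests (evaluated at alpha divided by the
number of responses) and pairwise contrasts. Contrasts are *unprotected
LSD t tests* on the pooled within-group mean square with the decision
level Bonferroni-divided by the number of pairs -- the "Bonferroni
modified LSD" reading of a reduced-alpha LSD procedure, as opposed to
Tukey-type adjustment. Mean REMS episode length is tested with a plain
one-way ANOVA per interval, excluding animals without an episode
listwise (the exclusion count is reported, so the effective N of every
test is visible). Band-power curves are reduced to per-animal trapezoid
AUCs of the hourly mean relative power over each interval before testing.

### Degenerate response sets

Compositional responses make the naive MANOVA singular: the three normed
durations sum to 1, and the six normed transition frequencies both sum
to 1 and obey the entry/exit flow balance of a closed interval (for each
state, entries equal exits up to a boundary effect of at most one
count). The flow balance is *exactly* satisfied for most animals, so no
amount of data makes the within-SSCP invertible. The package handles
this with a deterministic degeneracy rule inside `wilks_manova()`: drop
zero-variance responses; drop the smallest-variance response while the
retained responses sum to a constant; then, while the scaled within-SSCP
has reciprocal condition number below 1e-8, keep shedding the
smallest-variance response. Every shed response is recorded in the
result (`$dropped`). For the duration MANOVA this reduces to the
conventional "drop one state" (WAKE is dropped a priori); for the
transition MANOVA it typically retains three effective responses. A
design this degenerate is a property of 3-state hypnograms, not of any
particular data set.

## The stability test

The stability hypothesis -- that one line's curve lies constantly
above another's across the experimental time -- is tested on the ZT1--23
grid. At each ZT point the *common median* across the group means is
subtracted; the test operates on the signed excesses. The signed excess
(value minus common median) is used rather than the positive part
max(0, value - median): the positive part discards the below-median half
of the information and breaks the antisymmetry of the test under group
exchange (the positive-part variant remains available for sensitivity
analysis). Group means across animals at each ZT hour are the paired
observations; the common median is taken across the group means, not
across all animals -- with three groups this makes the middle group's
excess zero at every point, which is the natural reading of a
three-curve display.

The paired excess differences are tested with a Wilcoxon matched-pairs
signed-rank test: zero differences dropped, ties mid-ranked. For up to
25 informative pairs the *exact* null distribution is used, computed by
dynamic programming over the doubled mid-ranks (a sign-flip permutation
distribution that remains exact under ties -- necessary because a
constant-sign difference series, the canonical "stable" configuration,
has all |d| tied and must still yield its exact tail p of 2^(1-n)); above
25 pairs a normal approximation with tie and continuity correction is
used. The label *stable* requires both significance at the nominal 0.05
and a constant sign of the difference in at least 90% of the paired
points; "continuously above" is not otherwise quantified, and the 90%
operationalisation is a package decision. The full screen (every band x
state and every ordered transition pair, for every group pair) is always
emitted without selection; a Benjamini-Hochberg column is appended for
reference but the headline flag deliberately uses the unadjusted level,
matching the nominal p < 0.05 convention of this analysis tradition.

## Problem sizes and test design

The validation suite runs entirely on synthetic data, at sizes chosen to
balance statistical resolution against desk-scale runtimes: the
full-cohort round-trip uses the study-sized 24 animals x 2 days x 20700
epochs; the stationary-law recovery uses a single-phase chain of about
10^6 epochs; oracle-equivalence checks use 1000 randomized small
fixtures; null calibration uses 5000 ANOVA and 2000 Wilcoxon replicates
(3 x 8 animals and 23 paired points, mirroring the study geometry); the
directional checks on the shipped presets use 100 independent master
seeds, plus 40 null cohorts with identical presets for the false-positive
rate of the stability screen. All randomness derives from one integer
seed; the default, 20110324, is fixed in the generator configuration.

## Known limitations

* The generator's Markov structure has geometric bout lengths; real bout
  survival is heavier-tailed, so absolute episode statistics should not
  be read as physiological predictions.
* The scorer is a transparent cascade, not a reimplementation of any
  published proprietary scorer, and has no real-data benchmark here; its
  90%+ round-trip accuracy is an internal-consistency result.
* With three vigilance states, the transitions MANOVA tests an
  effectively 3-dimensional response space; reported df reflect the
  retained responses, which are listed in every result object.
* EDF/NPZ signal I/O is not provided; hypnograms, features, metrics and
  results travel as documented CSV, and signals are in-memory objects.
* The two recording sessions are averaged, not modelled as repeated
  measures; day-by-line interactions are out of scope.
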