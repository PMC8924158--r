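---
title: "Methods: frequency tagging and ERP statistics for word segmentation EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency tagging and ERP statistics for word segmentation EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

# The paradigm

`entrainr` implements the analysis pipeline of a classic statistical
word-segmentation experiment adapted for passive (for example neonatal)
high-density EEG. Subjects hear a continuous stream of consonant-vowel
syllables at 4 Hz. In the *structured* stream the syllables are organized
into four trisyllabic pseudo-words, concatenated semi-randomly: within a
word the syllable-to-syllable transitional probability (TP) is 1, across a
word boundary it is about 1/3. The drop in TP is the only segmentation
cue. If the brain tracks only the syllable rhythm, spectral power and
inter-trial phase coherence (ITC) concentrate at 4 Hz; if it discovers the
trisyllabic chunks, a second component emerges at the word rate, 1/0.75 s
= 1.333 Hz. A *random* stream (same syllables, near-uniform TPs) and
silent resting-state periods serve as controls.

After familiarization, isolated test triplets probe what was retained.
Four conditions cross two violations relative to the trained words
A~i~B~i~C~i~:

| condition | template | final TP heard? | ordinal positions kept? |
|-----------|----------|-----------------|-------------------------|
| Word      | A~i~B~i~C~i~ | yes | yes |
| Edge-word | A~i~B~i~C~k~ | no  | yes |
| Part-word | B~i~C~i~A~k~ | yes | no  |
| Non-word  | B~i~C~i~A~i~ | no  | no  |

The ERP contrast *ABx vs BCx* (Words + Edge-words vs Part-words +
Non-words) isolates ordinal/first-syllable encoding; *heard vs unheard*
(Words + Part-words vs Edge-words + Non-words) isolates TP-violation
responses.

# Stimulus generation

`build_lexicon()` returns one of three fixed word lists; the lists permute
the syllable-role assignment so test conditions are acoustically
counterbalanced across participants. Streams are symbolic event
sequences; no audio is synthesized.

`generate_structured_stream()` concatenates words under three rules: exact
balance (each word `duration/0.75/4` times), no immediate repetition, and
no two-word alternation longer than two pairs. The published stimulus
statistics (each of the 12 part-words 18-21 times per 180 s stream; TP
summaries with an SD near 0.01) additionally require near-uniform
word-to-word *transition* counts, which unconstrained quota sampling does
not produce (its part-word counts spread over roughly 14-26). The sampler
therefore draws each successor among the currently least-used transitions,
with random tie-breaking and restart on dead ends; `generate_structured_streams()`
carries the transition-count state across a series of streams so the eight
30 s re-familiarization streams also pool to the published band (24-28).
One consequence is stated openly: the across-transition TP SD of a single
180 s stream comes out near 0.005, tighter than the 0.017 printed for the
original stimuli, which evidently balanced a little less aggressively. The
means, the per-stream bands and the pooled bands all match.

Two TP estimators are provided by `empirical_tps()`. The row-normalized
version (`denominator = "transitions"`) makes each word's outgoing
probabilities sum to 1, so the mean of the 12 between-word TPs is exactly
1/3. The `"occurrences"` version divides by the antecedent's occurrence
count; the stream-final token then has one fewer outgoing transition than
occurrences, giving (4 - 1/60)/12 = 0.3319 for one 180 s stream and
(4 - 8/80)/12 = 0.3250 pooled over eight 30 s streams — precisely the
printed values of 0.332 and 0.325. The occurrence estimator is therefore
the one the audit reports against the published numbers.

`build_session_schedule()` lays out the full protocol: 60 s resting state,
120 s random stream, 180 s structured stream, eight series of (30 s
structured stream, 2.5 s silence, 16 isolated test words with ISI uniform
in [2, 2.5] s), then 120 s random and 60 s resting state again — 128 test
events, 4 per condition per block.

# The synthetic EEG model

`simulate_recording()` builds channels-by-samples data (microvolts, 250 Hz
by default) as an exactly linear sum of:

* a **syllable-evoked kernel** (damped sinusoid: amplitude 4 uV, 6 Hz,
  40 ms latency, 60 ms decay) convolved with every syllable onset — the
  4 Hz steady-state response;
* a **word-rate kernel** (slower damped sinusoid, amplitude
  `word_rate_amplitude`, default 2 uV) at word onsets inside structured
  segments only, gated per onset by a sigmoid in *cumulative structured
  exposure* with half-rise at `learning_onset_s` (default 120 s, emulating
  learning after about two minutes) and width `learning_width_s` (20 s);
* **test-word ERP components**: raised-cosine bumps over 0-0.4 s whose
  amplitude differs between ABx and BCx conditions (default 2 vs 0 uV),
  plus an optional late component;
* **1/f^a background**: spectrally shaped Gaussian sources (default 8,
  exponent 1, 3 uV each) mixed to channels through dipolar topographies;
* **white sensor noise** (1 uV per channel); and
* **artifacts**: Poisson-timed boxcar steps (~0.5 s) and spikes at
  +-500 uV on a random 30% channel subset, about one per minute —
  deliberately above the rejection threshold.

Topographies are projections of electrode positions onto random dipole
axes — spatially smooth, which is what the cluster statistics need, with
no claim of anatomical realism. The stimulus-locked topographies derive
from `topo_seed` (held fixed across a simulated cohort, because real
effect topographies are consistent across subjects), while `seed` varies
the noise per subject. Because every component draws from its own derived
seed, zeroing one amplitude never changes another component's
realization: the simulation is bit-reproducible and exactly linear, which
the tests assert.

What a green test does *not* establish: the simulator has no sleep-stage
microstructure, no volume conduction, no coarticulation-induced latency
jitter, and artifacts far simpler than real infant movement. Green means
the *analysis* recovers what the signal model put in, at the published
protocol's geometry and rates.

The montage is a golden-angle (Fibonacci) lattice on an upper hemisphere
(default 128 channels, 6 cm radius). Note that 128 points on that
hemisphere sit ~1.4 cm apart, so the 3 cm adjacency threshold yields ~14
neighbors per channel — denser than a real infant net, whose published
average is 4.2; the threshold is a parameter, and the cluster test only
requires the graph to encode spatial smoothness.

# Preprocessing

Entrainment chain: band-pass 0.1-40 Hz, resample to 300 Hz (an integer
225 samples per 0.75 s triplet), high-pass 0.2 Hz, cut consecutive 0.75 s
epochs from each segment start, reject epochs whose peak-to-peak exceeds
400 uV on any channel. ERP chain: band-pass 0.5-20 Hz, epoch [-1.50,
3.25] s around test-word onsets, reject, average-reference, divide each
epoch by its pooled standard deviation (one scalar per epoch, preserving
topography), baseline-correct.

Numerical choices. Filtering multiplies the spectrum by a zero-phase
Butterworth-magnitude response (order 12, ~72 dB one octave out of band),
zero-padded to a 5-smooth FFT length; this gives exactly zero phase lag at
the cost of acausal edge ringing confined to the recording ends.
Resampling is band-limited FFT interpolation, inherently anti-aliased.
The amplitude-threshold rejector is a documented stand-in for full
artifact-correction pipelines; it is sufficient here because the simulator
controls the artifacts. Subject inclusion thresholds are configuration:
at least 6 usable 0.75 s segments per condition (entrainment) and 12
trials per condition (ERP).

The baseline phrase for test words admits two readings; both are
implemented. The default takes the silent interval from 2.25 s after the
previous test word's onset to the current onset (about 0.5-1 s long,
inside the ISI), with [-0.25, 0] s for a block's first word; the
alternative (`baseline = "fixed"`) is a 2.25 s window ending at onset.

# Entrainment quantification

Retained 0.75 s epochs are concatenated in chronological order into
non-overlapping 7.5 s epochs (10 triplets, 30 syllables). At 300 Hz this
gives a 2250-sample FFT with 1/7.5 Hz resolution, so the word rate and
the syllable rate fall exactly on bins 10 and 30 — with a rectangular
window (no taper) there is no spectral leakage at the targets, which the
tests verify (>99.9% of a pure tone's power in one bin).

Long epochs are average-referenced, normalized, and denoised with DSS:
PCA on the total covariance (keep 30, whiten), then PCA on the covariance
of the trial-averaged data in whitened space (keep 6, ranked by evoked
reproducibility), projection onto those components and back to channel
space. If the reproducible signal has rank at most 6, DSS is the
identity on it; pure noise can only lose evoked power — both are tested.
By default DSS is fit per condition (and refit per sliding window); both
are switchable.

**Evoked power** is the power spectrum of the trial average. **ITC** is
the magnitude of the mean unit phasor across trials, in [0, 1]. Both are
scored against local noise:

* power: OLS fit of log P on log f over the 12 adjacent bins (6 per
  side = 0.8 Hz; target excluded), score = (log P at target - fitted) /
  SD of the fit residuals. Since OLS residuals have zero mean, this is
  the published "(log P - mean noise) / SD noise" form, made
  dimensionally consistent;
* ITC: plain z-score of the target bin against the 12 adjacent bins.

Under a signal-free simulation the power score is zero-mean with SD near
1.28 (the log of a two-degree chi-square is left-skewed; the acceptance
suite measures SD within the stated 1 +- 0.3 band at 400 replicates), and
the ITC score is close to standard normal. One degenerate case is
resolved explicitly: a spectrum lying exactly on a power law has zero
residual SD, and the score is defined as 0 there (no excess) rather than
0/0.

The learning curve repeats the analysis in 120 s windows stepped by 1.5 s
along the concatenated epoch timeline (resting, random, structured; test
periods are never epoched), each window labeled by its central time — the
first full window is centered at 60 s. A 120 s window is the compromise
between time resolution and having 16 long epochs per window.

# Group statistics

Electrode-wise SNR is tested against zero with a one-sided t-test across
subjects and Benjamini-Hochberg FDR correction across electrodes (the
"FDR" of the protocol, taken as BH, the field default; correction is per
frequency and measure, not pooled). The condition comparison pools the
electrodes significant in *any* condition at a given rate, averages each
subject's SNR over that union, and runs a one-way repeated-measures ANOVA
(sphericity assumed, matching the uncorrected df the protocol reports)
with Bonferroni-corrected paired post-hocs.

# ERP cluster statistics

Per subject, trials are averaged by condition; a contrast's side is the
mean of its two condition averages. Paired t-values are computed per
(channel, sample) in two separate search windows, [0, 0.5] s (effects
attributable to the first syllable) and [0.5, 2.75] s (TP-violation or
offset effects), with no correction across windows, as in the original
reporting. Points with |t| above the two-sided 0.05 quantile are
clustered by electrode adjacency (Euclidean distance <= 3 cm), temporal
contiguity, and matching polarity; cluster mass is the summed t. The
"minimum size of two" is read as >= 2 connected (channel, time) points —
the weakest faithful reading; `min_channels = 2` gives the stricter one.
The null distribution is the maximum absolute cluster mass over random
within-subject sign flips of the difference waveforms (the standard exact
scheme for a paired design, which the protocol leaves unstated), with
p = (1 + #{null >= |mass|}) / (1 + n_perm) and 5000 permutations by
default. The implementation is checked against a brute-force
connected-components oracle and against exact enumeration of all 2^5 sign
patterns on a 5-subject fixture.

The per-block time course averages the side difference over a cluster's
points, per subject and block, including a subject-block point only when
both sides retain at least 3 of their 8 trials in that block.

# The demo cohort and scaling

`run_demo_cohort()` simulates a cohort (default 20 subjects), runs both
analyses end to end, and writes TSV reports stamped with the config hash
plus advisory figures. The default montage for the demo is 32 channels,
not 128: the analysis is channel-count agnostic and a 128-channel,
13-minute, 250 Hz, 20-subject run does not fit a one-CPU desk budget.
For the same reason the demo's sliding step defaults to 30 s (1.5 s at
full resolution, selectable in the config) and its permutation count to
1000 (5000 in the operation default). The test suite runs everything at further reduced size —
fewer channels, shorter synthetic epochs, lower simulated rates — while
keeping the replicate counts of the calibration criteria at their stated
values; each test notes its scaling.

# Known limitations

* Streams are symbolic; audio-level cues (coarticulation, the 5 s
  amplitude ramps) are out of scope.
* The artifact rejector is a threshold stand-in, not a correction
  pipeline; bad-channel interpolation and ICA are not implemented.
* The sliding-window timeline is the concatenation of *retained* epochs;
  with heavy rejection its window centers drift relative to nominal
  session time.
* The power-SNR null distribution is heavier-tailed than standard normal
  (SD ~ 1.28); electrode-wise tests use the t statistic across subjects,
  which does not assume unit scale.
* Sphericity is assumed in the ANOVA (uncorrected df), matching the
  protocol's reporting.
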