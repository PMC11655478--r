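---
title: "Burst, network-burst and parameter-model methods in meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst, network-burst and parameter-model methods in meaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

meaburst analyzes multi-well MEA recordings of cultured neuronal networks,
with a focus on hippocampal-type cultures whose network bursts decompose
into *reverberations* — short high-frequency spike clusters that follow
each other closely within one burst.  This vignette is the package's own
account of the methods: the detection rules and their edge cases, the
regression model, the synthetic generator, and the design decisions taken
where the conventions of acquisition software are underspecified.

## Spike detection

Baseline noise is estimated per channel as the mean and standard
deviation over two non-overlapping 200-ms segments "without activity".
Activity-freeness is operationalized deterministically: candidate
windows on a 50-ms grid inside the first `search_span_s` seconds
(default 10 s) are ranked by root-mean-square amplitude, and the two
lowest-RMS non-overlapping windows win.  A flat signal (zero variance in
the quiet segments) is a degenerate baseline and an error rather than a
silent zero-spike result.

Spikes are threshold crossings of the absolute deviation from the
baseline mean at `threshold_sd` (default 5) baseline SDs, so positive-
and negative-going deflections are treated symmetrically; negating a
trace changes nothing.  Two conventional details are not specified by
the acquisition software and are therefore explicit configuration with
defaults:

* a refractory dead time of 1 ms after each accepted crossing, and
* spike-time alignment at the extremum of the deviation within 2 ms
  after the crossing (`alignment = "extremum"`), with the raw crossing
  sample available as an alternative.

Recordings normally arrive hardware-filtered; an optional stage
(`apply_bandpass`) mirrors a typical acquisition chain (2nd-order
100 Hz high-pass, 4th-order 3.5 kHz low-pass Butterworth) for signal
synthesized from scratch.  A pre-filter that excludes channels whose
quiet-segment RMS exceeds a microvolt bound is available but off by
default, since real rigs apply it at acquisition time.  Baseline is
computed once per channel per recording; per-segment re-estimation is a
plausible alternative reading that we did not adopt.

## MaxInterval reverberation detection

`detect_reverberations()` implements the five-parameter MaxInterval
method in three phases over a channel's inter-spike intervals (ISIs):

1. a candidate opens at spike *i* when `ISI(i, i+1) <= max_start_ms`
   and extends while subsequent ISIs stay `<= max_end_ms` — the opening
   pair is inside the candidate, and a spike consumed by one candidate
   cannot open the next;
2. adjacent candidates whose gap (next first spike minus previous last
   spike) is strictly below `min_between_ms` are merged;
3. candidates shorter than `min_duration_ms` or with fewer than
   `min_spikes` spikes are discarded.

Events span first to last spike, treated as half-open `[start, end)`
intervals for gap and overlap arithmetic (a spike at an event's end time
is the event's last spike and counts as inside it).  The defaults
(15/20/25/20/5 ms and spikes) suit reverberating hippocampal cultures;
the `cortical_isi100` preset (100/100/200/20/5) widens the thresholds
for cortical cultures, whose bursts are slower and not reverberating —
on the same train its intervals contain the hippocampal-default ones.

Two conventions are underspecified in acquisition software and exposed
as switches with documented defaults: the phase order is
merge-then-filter (the common MaxInterval convention;
`phase_order = "filter_merge"` applies the duration/count filter first),
and all gap comparisons are strict (`< min_between_ms`, `< 300` ms).
Spikes that fall in a merged gap without belonging to either candidate
are not added to the merged event's spike count; the count is the sum
over the merged candidates.

Reverberations merge into **bursts** when the gap to the next
reverberation is strictly below 300 ms (`merge_events()`); a gap of
exactly 300 ms separates.  The same rule applied at the well level turns
network reverberations into network bursts.

## Network events

Given per-channel reverberations, a channel is **active** when its mean
firing rate reaches `active_mfr_hz` (default 0.1 Hz; a threshold of 0
degrades to "any spike").  Candidate network events are connected
components of temporal overlap among active channels' reverberation
intervals — no time bins are involved, which keeps the rule
deterministic and scale-free.  A candidate is accepted when

* at least `ceil(participation_fraction * n_active)` distinct channels
  contribute (default two-thirds), and
* at some instant, at least
  `ceil(simultaneity_fraction * participation_threshold)` of its
  reverberations are simultaneously open (sweep-line maximum; default
  one-half).

"Of which at least half" is read against the required two-thirds cohort;
`simultaneity_base = "actual"` reads it against the channels actually
participating instead.  Ceilings are used for every fractional count and
ties at exact equality are accepted.  A single-channel well degenerates
gracefully: both thresholds become 1 and every reverberation is its own
network reverberation.

## Outcome measures

`compute_well_metrics()` returns the eight per-well measures in four
categories: mean firing rate (MFR, spikes/s averaged over active
channels; a flag averages over all channels instead), percentage of
random spikes (%RS: spikes of *any* channel outside every network-burst
span, as a fraction of all recorded spikes), network burst rate
(bursts/min), network inter-burst interval (NIBI, mean quiescence from
one burst's end to the next one's start — a flag switches to
start-to-start) with its coefficient of variation (sample SD over mean),
mean network-burst duration, mean network-reverberation duration, and
network burst composition (mean network reverberations per network
burst, ≥ 1 whenever defined).

Undefined measures are `NA`, never 0: NIBI needs two bursts, its CoV
needs two intervals (three bursts), and the duration/composition
measures need one event.  The %RS denominator counts all recorded
spikes, including those on inactive channels; this choice is recorded in
the output metadata of the analysis rather than hidden.

## The parameter-regression model

The three data-dependent MaxInterval parameters (max-start, max-end,
min-between) are regressed from 5-s windows; `min_duration_ms` and
`min_spikes` stay fixed configuration.  A window of 50,000 samples at
10 kHz becomes one of three inputs: the min-max-normalized signal
averaged in bins of 30 (length 1667, `signal30`) or 100 (length 500,
`signal100`), or the spike raster binned by 30 (`spikes30`).  The spike
input is binarized per bin by default (any-spike indicator) because the
inputs are conventionally binary; mean binning is a flag.  The final
factor-30 bin averages the 20 remaining samples; short windows are
right-padded with zeros first; a window with zero dynamic range
normalizes to all zeros with a warning.

The regressor is a compact 1-D CNN — two valid-convolution blocks (16
then 32 filters, kernel 7, ReLU, max-pool 4), a dense ReLU layer of 64
and a linear head of exactly 3 outputs — trained with mini-batch Adam
(learning rate 1e-3, batch 32) on the MSE of the parameters in
milliseconds.  The modest capacity matches the few-hundred-sample scale
of realistic training sets; every layer dimension is configurable, and a
seeded random search over a declared grid is easy to script on top.
Targets are regressed in raw milliseconds by default since the three
share a scale; `standardize_targets` z-scores them on the training split
(inverted at prediction time) for cases with strongly differing
magnitudes.  Everything — initialization, shuffling, splits — derives
from one seed, and two runs with the same config are identical.

Predictions are clipped to bounds (defaults: start and end in
[2, 200] ms, between in [2, 500] ms) before use; they are kept as reals
for detection and rounded to integers only when exported to training
containers, whose storage convention is integer milliseconds.

### The burst-overlap error and "custom accuracy"

Parameter MSE does not say whether the *bursts* found with predicted
parameters match the bursts found with the target parameters, which is
what actually matters.  The burst-overlap error compares binary burst
occupancy arrays,

$$A = \frac{\sum_i |b_p[i] - b_t[i]|}{\sum_i b_t[i]},$$

normalized by the target's active timestamps so that an all-zero
prediction scores 1 rather than looking nearly perfect on a sparse
array; an all-zero *target* makes the ratio undefined and is an error.
As printed, $A$ is a discrepancy (0 = perfect).  The learning-curve
"custom accuracy" is `max(0, 1 - A)`; both quantities are reported so
there is no ambiguity about direction.  The measure is asymmetric in its
arguments unless both arrays carry the same number of active timestamps;
the test suite pins this down.

In this package's experiments (reproduced by the test suite and
`scripts/acceptance.R`), the `signal30` variant's validation MSE
plateaus near the conditional-mean level while its held-out custom
accuracy is high: around comfortably-optimal generating parameters,
burst detection is insensitive to moderate parameter error, and
mean-binning largely cancels the biphasic spike waveform so the binned
signal carries little ISI information.  The `spikes30` raster input, by
contrast, supports genuine parameter learning (its validation MSE falls
well below a shuffled-label control's).  This is the package-level
restatement of why a burst-level score, not parameter MSE, is the right
currency for this task.

### Applying a model to full recordings

`analyze_with_model()` cuts each channel into consecutive
non-overlapping 5-s windows, predicts parameters per window (from the
raster for `spikes30`, from the raw trace for the signal variants), and
runs MaxInterval within each window.  How window-level predictions
should drive full-length recordings is genuinely open; per channel and
window is the reading adopted here, with one repair at the seams:
reverberations abutting a window boundary merge across it when their gap
is below the mean of the two windows' predicted `min_between`.  A
recording shorter than one window is processed as a single padded window
with a warning, and channels without spikes trigger no prediction at
all.  Downstream stages are byte-identical to the default path, so a
model that constantly predicts (15, 20, 25) reproduces the
default-parameter analysis exactly.

## The synthetic well generator

`generate_well()` emulates what the detector is meant to face:
12-channel wells at 10 kHz in which network bursts recur after
Gamma-distributed quiescent intervals (default mean 6 s, shape 4 — about
nine bursts per minute), each burst holds `1 + Poisson(2)`
reverberations, and each participating channel (probability 0.85,
onset jitter SD 5 ms) realizes every reverberation with its own spikes:
counts around 10 (floored at `min_spikes`), ISIs from an exponential
(mean 6 ms) truncated to 0.8 × the *smaller* of `max_start`/`max_end`,
redrawn until the span satisfies `min_duration`.  Inter-reverberation
gaps are uniform in (60, 280) ms with the lower end raised above
1.05 × max(`max_start`, `max_end`, `min_between`); an infeasible range
is a configuration error.  Background spikes (0.2 Hz per channel) and
intra-burst noise spikes (2 Hz in reverberation gaps) are thinned so
that every isolated spike keeps a guard distance of
1.05 × max(`max_start`, `max_end`) from all other spikes.

These choices make the generating parameters *comfortably optimal*: by
construction, running MaxInterval with them reproduces the ground-truth
reverberations exactly — the synthetic analogue of an expert's ideal
parameter choice, giving an objective label where real datasets rely on
expert judgment.  The truncation bound deliberately uses the smaller of
the two ISI thresholds (not `max_start` alone) because independently
drawn training parameters can place `max_end` below `max_start`, and an
ISI between them would split a ground-truth reverberation.  Network
ground truth is recomputed from the per-channel ground truth through the
standard network rules rather than stored independently, so there is a
single source of truth.  Rendered voltage places a biphasic ~1-ms
waveform (dominant negative trough, normalized extremum at the spike
time) scaled by a per-spike amplitude draw (mean 40 µV, SD 8, floored at
8 × the noise SD of 3 µV) on Gaussian noise, so ±5 SD detection recovers
the trains.

Training windows (`generate_training_dataset()`) are single-channel 5-s
realizations of the same machinery with per-window parameters drawn
uniformly from configurable ranges (defaults: start 8–30 ms, end
10–40 ms, between 15–60 ms); every stored window contains at least one
reverberation, times are quantized to the sample grid consistently in
the spike and burst blocks, and the self-consistency property —
burst-overlap error exactly 0 under the window's own parameters — is
asserted over hundreds of windows in the test suite.

What the generator does **not** emulate: electrode geometry and
position-dependent amplitudes, spike waveform diversity and overlap
(sorting is out of scope), development over days in vitro,
noise-induced merging of reverberations (real "optimal" parameters are
marginal, not comfortable), and channel-specific firing phenotypes.
Passing tests on synthetic wells therefore demonstrate the correctness
of the rules and the trainability of the model, not field performance on
any particular culture.

## Numerical choices and problem sizes

Gap and duration comparisons use a 1e-12 s slack where a strict/loose
boundary meets floating point; sweep-line concurrency counts ends before
starts at ties (half-open semantics) and treats zero-width intervals as
momentarily open.  Event tables round-trip through CSV at 1e-9 s or
better; HDF5 recordings round-trip bit-for-bit.  The test suite and the
acceptance script size their simulations to run on one CPU in a few
minutes: 600-s wells for end-to-end recovery, 400–500 windows for
self-consistency and model training (30 epochs), and 1000 random trains
for the detector-versus-reference comparison.

## Known limitations

* The MaxInterval scan consumes the spike that closes a candidate, so a
  spike can never belong to two candidates; software that re-opens on
  the closing spike would differ on pathological trains where
  `max_start > max_end`.
* Baseline estimation assumes at least 400 ms of genuinely quiet signal
  inside the search span; recordings that burst continuously from t = 0
  yield an inflated SD and conservative detection.
* The CNN is a compact, single-threaded implementation tuned for
  few-hundred-sample datasets; for orders of magnitude more data a
  dedicated deep-learning framework is the right tool, and the
  checkpoint format deliberately stores the architecture spec so a
  re-implementation can load the same description.
* `%RS` counts spikes from all recorded channels; pipelines that count
  active channels only will report slightly lower values on wells with
  sparse inactive channels.
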