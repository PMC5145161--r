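---
title: "Block-wise superparamagnetic spike sorting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-wise superparamagnetic spike sorting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Extracellular micro-electrode recordings mix the action potentials of
several nearby neurons with background noise, multi-unit "hash"
(spikes of many distant neurons too small to isolate), and — in
clinical settings — long stretches of non-neural artifact. *Spike
sorting* attributes each detected event to the neuron that fired it.
Two things make long recordings (hours to a whole night) especially
hard: the electrode drifts, so a neuron's spike amplitude and shape
change slowly over time, and contamination comes and goes, so any
global model of the channel is wrong for part of the night.

`blocksort` addresses this with a block-wise design: spikes are
detected and cleaned, cut into blocks of a fixed *count* (not a fixed
duration), each block is sorted independently by superparamagnetic
clustering, leftover spikes are assigned by template matching at two
stages, clusters are screened by rule-based artifact criteria, and
finally clusters are merged — within and across blocks simultaneously
— into groups that can track one unit across the entire recording.
Count-based blocks confine artifact storms to few blocks and keep the
per-block problem size constant; drift within one block is small, and
drift across blocks is absorbed by the merging stage.

# Detection and extraction

The trace is band-pass filtered at 300–1000 Hz with a 4th-order
Butterworth applied forward and backward (zero phase, so spike peaks
are not displaced). The detection threshold is `thr_mult` (default 5)
times the robust noise scale `median(|x|)/0.6745`, per channel.
Positive and negative threshold crossings are detected as separate
streams; negative-stream waveforms are sign-flipped so that all
downstream stages see positive peaks. No refractory period is
imposed; overlapping detections are resolved later by an explicit
rule. Waveforms are cut to a 2 ms window (48 samples at 24 kHz) with
a quarter of the window before the peak, and aligned to the peak on a
3× cubic-spline-upsampled grid before decimating back. Events too
close to the recording edges are dropped and counted.

Note one consequence of the narrow analysis band: only a small
fraction of broadband noise power lies inside 300–1000 Hz, so the
detection threshold on a typical channel sits near the amplitude of
the multi-unit hash, and a large share of detections are hash and
noise events. This is the regime real micro-electrode channels are
in; the pipeline is designed to sort these events into their own
(multi-unit or artifact) clusters rather than pretend they do not
exist.

# Pre-sorting artifact rejection

Four event-level criteria, each evaluated on the original event set,
with the final keep-mask their conjunction:

1. **Rate** — events are counted in 500 ms bins with 250 ms hop
   (anchored at the recording start); every event covered by a bin
   with more than 100 events (a firing rate no single neuron
   sustains) is removed. Inequalities are strict.
2. **Amplitude** — events whose absolute extremum exceeds 1000 µV are
   removed (strict).
3. **Double detections** — within any pair of detections closer than
   1.5 ms, the waveform with the smaller maximum is discarded; chains
   are resolved by one deterministic left-to-right sweep comparing
   the current survivor with the next event.
4. **Concurrency** — with at least 10 channels available, 3 ms bins
   (1.5 ms hop) containing an event on at least half the channels are
   excluded on every channel. Action potentials are seen on one
   channel; movement and electrical artifacts hit the whole array.
   Below 10 channels the criterion is disabled, because with few
   channels genuine coincident firing would be deleted.

# Features and clustering

Each spike is decomposed with a 4-level orthonormal Haar wavelet
transform (one coefficient per sample). For every coefficient the
Kolmogorov–Smirnov statistic against a normal distribution with the
coefficient's own mean and SD is computed (Lilliefors-style, since no
reference distribution is available a priori); the 10 coefficients
deviating most from normality are the feature space. The intuition:
a coefficient that separates two neurons is bimodal, hence far from
normal; a noise-only coefficient is approximately normal.
Zero-variance coefficients get statistic 0; rank ties break toward
the lower coefficient index.

Clustering is superparamagnetic: each spike is a `q = 20`-state Potts
spin; spins interact along the union of the 11-nearest-neighbour
graph and a minimum spanning tree (which guarantees a connected graph
and hence a single cluster in the zero-temperature limit) with
strength `J_ij = (1/K) exp(-d_ij^2 / (2 a^2))`, where `a` is the mean
neighbour distance and `K` the mean degree. The model is simulated
with the Swendsen–Wang cluster algorithm (100 burn-in + 300
measurement sweeps per temperature) at 21 temperatures equally spaced
in [0, 0.2]. Clusters are read out per temperature from the pairwise
spin–spin correlations: pairs with correlation above 0.5 are linked,
and every point left on its own is then *captured* towards its
maximally correlated neighbour, as in the published construction of
the method. The capture step matters: without it, melted regions read
out as isolated points, whereas with it they fragment into the ragged
mid-size structure that the cluster-selection stage feeds on. All
randomness comes from a self-contained counter-based RNG seeded
explicitly, so a run is bit-reproducible regardless of R's RNG state
or the number of worker processes.

# Multi-temperature cluster selection

Low temperatures give one cluster, high temperatures give dust; real
units appear as clusters whose size is *stable* across a range of
temperatures. Iterating from the second temperature (the first where
a local maximum is defined) to the second-to-last, the clusters at
each temperature are ranked by size, and the `i`-th largest is
selected when its size is a strict local maximum over temperature at
that rank. Selected clusters claim their not-yet-claimed members;
spikes claimed at a lower temperature are never reassigned. At most
`C_max` selections per temperature, minimum size `S_min` (an absolute
count by default; values below 1 are read as a fraction of the block).

The strict local-maximum rule implicitly relies on Monte-Carlo size
jitter: on data with compact, well-separated clusters an exact
readout produces *exactly flat* size runs (no strict maximum exists
at all), and the largest child of any split inherits a monotone
non-increasing curve (born below its parent, it only sheds members).
Three deterministic stability clauses therefore extend the rule, all
reading the same rank-wise size table: the start of an exactly flat
run (equal size at the next temperature, different at the previous);
a material rise that persists (previous ≤ 0.9 s and next ≥ 0.75 s);
and a split-drop that persists (s ≤ 0.9 previous and next ≥ 0.75 s).
On gradually fluctuating tables none of these fire and the behaviour
is exactly the local-maximum rule. Two guards complete the rule: a
cluster holding more than 90% of the input is never selectable (size
jitter can make the undifferentiated root a formal local maximum, and
selecting it would freeze the whole subset into one cluster), and the
stability clauses require at most 50% of the input. The one case this
penalises — a genuinely homogeneous block that is one big cluster —
is left to the template-matching and residual stages.

# Splitting, template matching, merging

**Splitting.** Every selected cluster with at least `R_min` spikes is
re-clustered on its own members (feature selection and the
temperature sweep are re-run on the subset, so discriminative
directions within the cluster get a second chance); if at least two
subclusters emerge they replace the parent, and the procedure recurses
until no cluster qualifies or splits.

**Template matching.** Each cluster's mean waveform and variability
`s = sqrt(sum_i var(x_i))` (root of summed per-sample variances, so
`f·s` is commensurable with a Euclidean distance in µV) are computed.
An unassigned spike joins the *nearest admissible* cluster: clusters
admit a spike when the Euclidean distance to their mean is below
`f·s`, and among admitting clusters the nearest wins. (The
alternative reading — check only the globally nearest cluster's
radius — differs only when the nearest cluster rejects a spike that a
slightly farther one would admit; nearest-admissible is the more
permissive and the more symmetric choice.) Within a block the radius
is conservative (`f1 = 0.75`) because a second, generous pass
(`f2 = 3`) runs later across blocks, pooling candidate clusters from
all blocks. Spikes never assigned end up in the residual cluster
(id 0).

**Post-sorting artifact criteria** flag a cluster when any of the
following holds: its mean waveform has more than 5 local maxima
(sinusoidal noise); the ratio of the largest to second-largest local
maximum — counting only maxima at least 0.3 ms apart — is below 2;
the amplitude range of the second half of the mean waveform exceeds
the global maximum (activity not locked to the aligned peak); or the
per-sample standard error of the mean averaged over samples exceeds
2 µV (no stereotyped waveform at all). Local maxima are strict
interior sign changes of the first difference, unsmoothed by default.
The third criterion compares a range to a point value, which is how
it is stated; it is sensitive to deep, late repolarisation troughs,
so the simulator keeps template trough depths in the physiological
0.30–0.45 of peak. The SEM criterion is an *absolute* threshold: on
data with deliberately inflated waveform noise (like the multi-hour
protocol below) it would flag genuine clusters, so `sort_channel()`
takes `flag_artifacts = FALSE` for artifact-free simulations — the
same choice the evaluation protocol this package follows made.

**Merging.** All non-artifact clusters from all blocks are merged
agglomeratively, within and across blocks simultaneously: repeatedly
merge the pair of groups with minimal distance between mean
waveforms, recompute the merged mean (spike-count weighted, with
per-sample sums of squares combined exactly), stop when the minimum
exceeds `C_stop`. The distance is normalized by the pooled
variability `s` of the candidate pair, putting `C_stop` on the same
scale as the template-matching radii; a `merge_metric = "raw"` option
gives plain µV distances. Merging edits only the cluster table —
every spike keeps its original cluster id — so any grouping can be
undone exactly (`ungroup_sorting()`).

# The simulator

`make_dataset()` builds a ground-truth recording: per-neuron Poisson
trains (2 ms absolute refractory) convolved with parametric
difference-of-Gaussians templates, summed linearly (overlaps kept,
labels preserved), plus white background noise, multi-unit hash
(small randomly scaled spikes at `mua_rate` per channel), and
injected artifacts: sinusoidal line-noise bursts, high-amplitude
transients, and cross-channel transients hitting a configurable
fraction of the array. Template shape parameters (peak width, trough
delay, width and depth, initial dip) are spread evenly across neurons
and permuted, so every neuron has a distinct waveform, as in template
banks drawn from real recordings. Two realism constraints worth
stating: template widths are chosen so the spike's spectral energy
lies inside the 300–1000 Hz analysis band (narrower peaks would reach
the sorter as ring-dominated wave packets), and trough depths stay
at or below 0.45 of the peak (deeper troughs straddle the window
midpoint after filtering and would trip the tail-range artifact
criterion on genuine units).

What the generator does *not* emulate: bursting (ISI structure is
Poisson beyond the refractory period), electrode-specific noise
spectra (background is white), waveform non-stationarity other than
the multiplicative drift of the multi-hour protocol, and overlapping
spikes resolved as such (overlaps are summed and left for the
double-detection rule). Passing the validation suite therefore shows
the pipeline recovers band-compatible, shape-distinct, near-stationary
units under realistic contamination — not that it handles bursty or
strongly non-stationary units.

`make_multihour()` implements the long-recording protocol at the
level of extracted spikes: the base set is concatenated `n_cat` times
with shifted times, waveforms are multiplied by a drift factor rising
linearly from 1 to 1.5 over the whole span, and i.i.d. Gaussian noise
with SD equal to 20% of the maximum value attained in the base set is
added to every waveform sample.

# Reference configurations and problem sizes

The validation suite and `scripts/acceptance.R` run two fixed,
documented configurations (`ref_recording_config()`,
`ref_concurrent_config()`, `ref_multihour_base()` with
`ref_sort_params()` / `ref_multihour_params()`):

- **Screening channel**: 5 neurons (peaks 60–110 µV over 10 µV
  broadband noise, i.e. band-referred SNR around 8; rates 0.5–3 Hz),
  10 minutes at 24 kHz, 20 Hz hash, 20 sinusoidal 900 Hz bursts
  (inside the analysis band, so they survive filtering and form
  stereotyped artifact clusters) and 30 transients of 3 mV (above the
  1 mV exclusion criterion *after* filtering — a 1.5 mV broadband
  transient would arrive below 1 mV and test nothing). Sorted with
  `C_max = 7`, `R_min = 500`, `N_rep = 2`, `C_stop = 1.2` — the
  setting appropriate for short simulations with many clusters.
- **Concurrency array**: 16 channels, 60 s, 30 moderate transients
  shared by half the array.
- **Multi-hour base**: two template neurons at 110 and 140 µV with
  maximally distinct shapes, 2–2.5 Hz, 3 minutes; concatenated 12
  times (≈ 2 h equivalent) with drift to 1.5 and 20%-of-max noise.
  Amplitudes are deliberately similar and large: the protocol's added
  noise scales with the *maximum* value of the base set, so a small
  unit next to a large one is drowned by the large one's noise, and
  under heavy isotropic noise shape contrast is what remains. Sorted
  with `N_block = 2500` — scaled so one block spans roughly one
  concatenated repetition (≈ 4% amplitude drift per block), which
  preserves the design premise that a block is locally stationary —
  and `C_stop = 1.4`, `flag_artifacts = FALSE`.

These sizes keep the complete suite within tens of minutes on one
CPU while exercising every stage at realistic event counts
(≈ 12 000 detections on the screening channel, ≈ 27 000 spikes and
11 blocks in the multi-hour set).

# Evaluation

`score_hits()` matches sorted spikes to ground-truth spikes by time
(one-to-one nearest neighbour within 0.5 ms, earlier spike wins
ties) and evaluates every merged group against its plurality neuron:
*purity* (fraction of the unit's spikes from that neuron),
*completeness* (fraction of the neuron's spikes captured). A unit is
a *hit* when both reach 50%.

`response_score()` implements the screening-session statistic: spike
counts of each presentation in 19 overlapping 100 ms bins covering
the 1 s stimulus window, each bin compared against the pooled
baseline (all 500 ms pre-onset intervals of the session, tiled into
100 ms sub-bins so both samples are counts over the same window
length) with a one-sided Mann–Whitney U test — a response is an
*increase* over baseline; the paper this statistic comes from does
not state a sidedness, and the one-sided choice matches the
"response" semantics. The 19 p-values are Benjamini–Hochberg
adjusted and the score is their minimum; a (unit, stimulus) pair is a
response when the score is below 0.001 *and* the unit fired in at
least 4 presentation windows. Under a homogeneous Poisson null the
empirical false-positive rate of the full procedure is below 0.005
(checked over 1000 simulated null units in the test suite).

# Containers

Spike sets and sorting results are stored as directory containers —
CSV tables plus a JSON metadata sidecar — and continuous recordings
as flat binary (lossless float64, or int16 with per-channel gain in
µV/bit) with a JSON sidecar. Times are milliseconds from recording
start as 64-bit floats; µV is the only internal voltage unit, and
every reader validates its schema (a container missing a required
column is an error, never a silent default). The configuration file
is a single YAML document mirroring the parameter constructors;
unknown sections or keys are errors.

# Known limitations

- Single-wire electrodes only; no joint detection across tetrode
  channels.
- The selection guards mean a block that is genuinely one homogeneous
  cluster relies on template matching across blocks; a single-block
  recording of a single unit can end up largely residual.
- Units closer than roughly twice the within-cluster
  nearest-neighbour scale in feature space are not resolved by the
  temperature sweep; under the multi-hour protocol's 20%-of-max noise
  this corresponds to units of similar amplitude *and* similar shape.
- The tail-range artifact criterion is stated as a range-vs-maximum
  comparison and is sensitive to deep late troughs; clusters flagged
  solely by it deserve a look before being discarded.
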