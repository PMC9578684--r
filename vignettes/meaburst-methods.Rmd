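---
title: "Methods: spike-train analytics for long-term HD-MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analytics for long-term HD-MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## Scope and data model

`meaburst` analyses *sorted* spike trains from long-term recordings of
developing neuronal cultures on high-density microelectrode arrays
(HD-MEAs). Everything upstream of spike times — filtering, spike sorting,
waveform processing — is assumed done by dedicated tools; the package
consumes per-unit spike-time tables with quality-control (QC) attributes,
soma-tracking tables, and produces curated sessions, activity metrics,
burst analytics, activity maps, displacement analytics and nonparametric
condition comparisons.

Units and conventions, used everywhere without exception:

* time in **seconds**, rates in **Hz**, coordinates in **micrometres**,
  culture age as integer **days post induction (dpi)**;
* recording windows are half-open `[t_start, t_stop)`, so a spike exactly
  at `t_stop` is invalid and every rate denominator is unambiguous;
* CSV is the canonical exchange format: spike tables
  (`unit_id,time_s[,isi_violation_rate,snr,firing_rate,electrode_index]`)
  and tracking tables (`track_id,dpi,x_um,y_um`, with an importer for the
  ImageJ Manual Tracking column set plus a slice-to-dpi map).

## Unit curation and the active-unit rule

A sorted unit is removed when **any** of the following holds: its
interspike-interval (ISI) violation rate is above 0.2, its
signal-to-noise ratio (SNR) is below 5, or its firing rate is below
0.1 Hz. Boundary semantics are strict and asymmetric on purpose — a unit
*at* 0.2 violations, *at* SNR 5, or *at* 0.1 Hz is kept. The
ISI-violation rate is defined here as the plain fraction of ISIs shorter
than a 1.5 ms refractory period (configurable): the threshold reads as a
fraction, so the simple fraction — not a rate-corrected contamination
estimator — is the default. SNR must be supplied as an input attribute;
it cannot be recovered from spike times.

Separately, a unit counts as *active* when its firing rate is strictly
above 0.1 Hz; a unit at exactly 0.1 Hz is inactive. Activity is a
reporting classification, not a curation rule.

## Firing-rate and instantaneous-frequency analytics

The AP frequency of a unit is spike count over recording duration. The
instantaneous frequency of each AP pair is the inverse of its ISI,
timestamped at the *second* spike of the pair, because an ISI is only
known once its closing spike occurs (this affects only time-resolved
displays, never fractions). Frequency-domain histograms assign each
active unit to one half-open bin `[lo, hi)` of its AP frequency, default
edges `{0, 1, 2, 5, 10, Inf}` Hz.

Fast-spiking classification uses two thresholds: an *event* is fast when
its instantaneous frequency is strictly above 150 Hz, and a *unit* is
fast-spiking when at least 5% (inclusive) of its events are fast. Events
above 600 Hz still count but are flagged as implausible. The session-level
mean instantaneous frequency averages per-unit means (one value per
neuron) with its SEM; pooling all events instead is available as an
option, since "average instantaneous frequency" is ambiguous between the
two — per-unit averaging is the default because the downstream statistics
treat the neuron as the unit of analysis.

## Poisson-surprise burst detection

For a window of duration $T$ containing $N$ spikes from a unit with mean
rate $\lambda$ (count over recording duration, fixed during scanning),
the surprise is

$$S = -\log P, \qquad
  P = \sum_{n=N}^{\infty} e^{-\lambda T} \frac{(\lambda T)^n}{n!},$$

the upper tail of the Poisson distribution, evaluated through the
numerically stable log-tail routine (regularized incomplete gamma). The
natural logarithm is the default, so the minimum surprise of 4
corresponds to a tail probability below $e^{-4} \approx 0.018$; base-10
is configurable.

The scan protocol: a candidate starts at the first of three consecutive
spikes whose two ISIs both fall below half the train's mean ISI (the mean
ISI is computed once, globally); spikes are appended while the next ISI
does not exceed the mean ISI; $S$ is evaluated at every candidate length
of at least 4 spikes, with $T$ the span from first to last candidate
spike, and the length maximizing $S$ is selected — ties go to the
shortest extension, for determinism and parsimony. The candidate is
emitted only if $S \ge 4$, its duration is at least 20 ms and it has at
least 4 spikes (all configurable); the thresholds are applied *after*
maximization. Scanning resumes at the spike after an emitted burst, or at
the next spike after a rejected candidate, so emitted bursts are disjoint
and time-ordered. Backward refinement of the burst start (shedding
leading spikes) is available behind `refine_start = TRUE` but off by
default, since the default protocol does not describe it.

Per-unit summaries report burst frequency (bursts per second of
recording), mean burst duration (undefined when there are no bursts) and
the percentage of the unit's APs that fall inside burst events.

### Network bursts

The criterion for a *network* burst is a declared convention, exposed in
`network_burst_config()`: time is binned at 0.1 s, and bins where at
least `max(5, ceiling(0.2 × active units))` units have an ongoing burst
are merged (adjacent qualifying bins) into network-burst intervals.
Members are the units whose bursts overlap the interval; a unit
*participates* in network bursting when at least one of its bursts
overlaps at least one interval.

A known limitation of any binned-concurrency convention: when many units
burst independently at realistic rates (50 units at 0.2 bursts/s), brief
chance co-activations of 10+ units occur a few times per 5-minute
session and are indistinguishable *by concurrency alone* from genuine
network events at the default threshold — in synthetic sessions they
inflate the raw event count by roughly 5–15% relative to injected
events, while events matched to injected ones agree within a few
percent. Raising the concurrency fraction suppresses them at the cost of
missing weakly participating events; the trade-off belongs to the
analyst and the config.

## Array model and activity maps

The default grid is 120 × 220 electrodes at 17.5 µm pitch — 26,400
electrodes covering 3.85 × 2.10 mm using the cell model (count × pitch
per side). Indexing is 0-based and row-major with the origin at the
top-left and y increasing downward, so maps overlay microscopy frames
directly. An electrode is *active* when its AP frequency is strictly
above 0.1 Hz **and** its mean spike amplitude strictly above 20 µV; the
network assay selects up to 1,024 of the most active electrodes, sorted
by rate with ties broken by ascending index. The full-scan emulator
partitions the array into `ceiling(total/block_size)` consecutive blocks
(default 1,000 electrodes, 30 s dwell) — 27 blocks for the default grid;
vendor firmware uses its own, unknown block geometry (29 iterations are
reported for the real system), so block size and count are configurable
and the arithmetic partition is the default. Activity maps store raw
per-electrode rates; any min–max color normalization is per-frame and
applied only at export, never stored.

## Displacement analytics

Interval displacements are Euclidean distances between consecutive
tracked positions. "Cumulative displacement" conflates two quantities,
so both are always computed and labelled: the *path length* (sum of
interval distances) and the *net* displacement (first to last sample);
path length dominates net by the triangle inequality and both are
invariant under rigid motions of the coordinate frame. Cohort
distributions use half-open bins (the 50–200 µm headline bin is
`[50, 200)`). The pitch relation `floor(displacement / pitch)` converts
a mean displacement to whole electrode pitches: 224 µm at 17 µm pitch is
13 electrodes. Neurons absorbed into clusters should be tracked as the
cluster centroid upstream; the importer consumes whatever track the
table provides.

## Condition comparison

Developmental time courses and baseline/treatment/washout pharmacology
are compared with the Kruskal–Wallis omnibus (tie-corrected H,
chi-square approximation) followed by Dunn's multiple-comparison post
hoc: pairwise z from mean-rank differences over the pooled ranking with
tie-corrected pooled variance, two-sided p adjusted over all pairs —
Bonferroni by default (Holm available), matching the "multiplicity
adjusted" behaviour of common GUI statistics software. Neurons are the
unit of analysis (one value per neuron, independent groups, no pairing
across conditions), α = 0.05, and summaries are mean ± SEM with the
n−1 convention. Units with no bursts are excluded from the
mean-burst-duration vector (their duration is undefined), but contribute
zeros to burst frequency and percent-in-burst.

## The synthetic-data generator

Because the recordings behind the pipeline are not deposited, validation
rests on a seeded generator with ground truth. One developmental stage is
parameterized by `stage_params()`; all randomness flows from one explicit
seed. Defaults describe a developed culture at network-assay scale and
were fixed once from the recorded regime: 50 units for 300 s, 2 Hz
Poisson background, 0.2 bursts/s per unit (per-neuron burst frequencies
around 0.2 Hz are typical of mature cultures), gamma-distributed burst
durations with mean 0.2 s (shape 4), 100 Hz within-burst rate, network
events at 0.05/s with 50% participation resampled per event and 20 ms
start jitter, 10% fast-spiking units firing 4 ms doublets after 25% of
their background spikes.

Three deliberate design choices keep the ground-truth labels meaningful:

* **Quasi-regular within-burst spikes.** Within a burst, spikes sit at
  the nominal ISI with ±10% uniform jitter rather than as a Poisson
  process: Poisson spacing at 100 Hz would put about half the
  within-burst ISIs under 6.7 ms, i.e. above the 150 Hz fast-event
  threshold, destroying the fast/slow separation the labels promise.
  Quasi-regular 100 Hz bursts cap instantaneous frequency at 125 Hz.
* **No overlapping bursts within a unit.** A burst injection (single-unit
  or network-driven) that would overlap an existing burst of the same
  unit within a 20 ms margin is skipped: one neuron cannot run two
  bursts at once, and interleaving two 100 Hz trains would create
  spurious ~200 Hz events. Superposition with the background remains
  additive, with near-coincident duplicates (< 0.1 ms) collapsed.
* **Membership resampled per event.** Each network event draws its
  participant set afresh, reproducing the partial participation seen in
  raster plots of developing cultures.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: bursty rate nonstationarity outside injected
bursts, refractory structure of background spiking, electrode-level
waveform noise and unit splitting/merging, correlated QC attributes, and
network events with structured (e.g. spatially organized) rather than
random membership.

Problem sizes used in the validation suite — chosen to exercise the
study-scale conditions while staying comfortably reproducible on a
laptop: surprise oracle agreement on a 50 × 14 grid of (N, λT);
detector-vs-enumeration equality on 500 random trains of up to 200
spikes; recovery on 50-unit/300-s sessions (one seed for burst
recall/precision, 20 seeds for network-event counts, 3 for fast-unit
labels); 1,000 null simulations at n = 50/group for type-I calibration;
and 50 seeded pharmacology experiments at 30 units/120 s, where effect
sizes (burst rate ×1.5, duration ×0.6) are large relative to sampling
noise by design.

## Numerical choices, degenerate inputs, known limitations

* The Poisson tail is evaluated in log space (`lower.tail = FALSE,
  log.p = TRUE`); the independent test oracle sums the series directly,
  switching between lower-tail-plus-`log1p` and direct upper-tail
  summation at `N − 1 ≈ λT` to avoid cancellation. Agreement is to
  ~1e-14 relative error.
* Surprise is 0 when N = 0; rate or window ≤ 0 is an error, not a
  silent 0.
* Trains with fewer than `min_spikes` spikes (or fewer than 3) yield an
  empty burst table, not an error; a perfectly regular train can never
  seed a candidate.
* Tie-breaks are deterministic everywhere: shortest extension on equal
  surprise, ascending electrode index on equal rate, first appearance
  order for unit identity.
* `findInterval`-based binning makes every histogram bin half-open with
  edge values promoted to the higher bin.
* The CSV writer prints times at nanosecond resolution (9 decimals);
  round-trips are exact at that resolution.
* The chi-square approximation to the Kruskal–Wallis p is a large-sample
  approximation; at total n ≤ 8 it can deviate from the exact
  permutation p by several percentage points.
* Chance co-activation inflates raw network-burst counts at high
  asynchronous burst rates (see above).
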