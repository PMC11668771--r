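---
title: "Attention-shift gaze metrics: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-shift gaze metrics: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeaoi)
```

## The measurement model

A screen-based eye tracker emits a stream of time-stamped gaze samples:
coordinates in screen pixels (origin top-left, y downward), per-eye validity
codes, and pupil diameters. `gazeaoi` scores each sample against a declared
stimulus — a set of AOI polygons plus a partition of the timeline into
blocks — and reduces the resulting label sequence to per-subject metrics.

Every sample receives exactly one label, decided in a fixed order:

1. `INVALID` — no eye valid (the coordinates are then meaningless);
2. `OFFSCREEN` — a valid gaze point outside the half-open screen rectangle
   `[0, width) × [0, height)`;
3. the first declared AOI whose polygon contains the point, boundaries
   included (first-declared wins if test AOIs overlap — a deterministic
   tie-break; real stimuli should not declare overlapping AOIs);
4. `VACANT` — on-screen, on no AOI.

This ordering makes the labels a partition: AOI counts + vacancy +
off-screen + invalid always sum to the number of samples, a conservation
law the test suite checks on hundreds of randomized recordings.

### Gaze counts and the dwell-time convention

One *gaze count* is one valid gaze sample. This is a deliberate, prominent
convention: commercial analysis software applies proprietary fixation-event
filters whose parameters are unpublished, so counts defined over "fixations"
are not reproducible from raw exports. Sample counts are. The cost is that
TGC scales with the sampling rate; the per-second series
(`per_second_series()`) and the vacancy *rate* are the rate-independent
normalisations, and total fixation time is defined as dwell time,

TFT(a) = TGC(a) × sampling interval,

so it inherits reproducibility at the price of including brief passes
through the AOI. For sensitivity analyses against event-filtered data an
optional dispersion-based pre-filter (`dispersion_prefilter()`) relabels
non-fixation samples as `INVALID`; it is off by default because the shipped
metrics are defined on raw samples.

### The attention-shift metrics

- **ASC** collapses the label sequence to AOI-only runs and counts adjacent
  runs with different names. `min_dwell_samples` (default 1, i.e. no
  debouncing — the most literal reading of "switches") optionally discards
  runs shorter than a dwell threshold before counting, suppressing
  single-sample flicker at AOI borders.
- **FAS/UAS** score pathway adherence. Each block of the joint-attention
  stimulus declares the AOI a typically developing viewer is expected to
  attend (tablet while it plays, the partner's face when it stops:
  tablet–face–tablet–face). FAS sums gaze counts on the favored AOI per
  block; UAS sums counts on competing AOIs. These are *counts along the
  pathway*, not discrete transition events: the event-based alternative is
  ill-defined at block boundaries and is not what the reported group
  tables tabulate. A configurable response window (first *N* ms of each
  block) is available because a reorienting shift, if that is the quantity
  of interest, lands early in the block; the default counts whole blocks.
- **AVC** counts `VACANT` samples. Its rate normalisation divides by
  vacant + AOI-labeled samples — attention that reached the screen — so
  tracker dropout and off-screen excursions affect neither numerator nor
  denominator, and the rate is invariant to appending invalid samples (a
  tested property).

## Inclusion filters

Two standard stages, both logged with the computed fraction and threshold:
recordings with screen-looking fraction below `segment_min` (default 0.25)
are dropped, then subjects whose retained-trial fraction (out of trials
presented) falls below `subject_min` (default 0.50). A "valid trial" is
defined as one that passes the segment stage; the denominator is trials
presented. A sample is screen-looking when at least one eye is valid and
the (binocularly averaged, when both eyes are valid) gaze point is
on-screen. Filtering is idempotent, also a tested property.

## Statistics and cutoffs

Group comparisons use the two-sided Wilcoxon rank-sum test with midranks
for ties: exact null enumeration for small tie-free samples, otherwise the
normal approximation with tie-corrected variance and continuity correction.
Sidedness is two-sided throughout, and no multiple-testing correction is
applied; the comparison table records how many tests it contains so readers
can apply their own.

Cutoffs come from two procedures, with provenance recorded because they
answer different questions:

- **regression-mapped** — fit metric on severity by least squares and
  evaluate the line at a clinical severity cutoff (default 5, the
  consensus ADOS-2 CSS threshold; configurable). The decision direction
  follows the slope's sign.
- **roc_scan** — evaluate every achievable threshold (midpoints between
  adjacent distinct values plus sentinels beyond the extremes) and take
  the Youden-optimal point, ties broken toward higher sensitivity, then
  lower cutoff.

Values exactly at a cutoff classify negative — "beyond the cutoff" is
strict. Every (cutoff, sensitivity, specificity) triple the scan emits is
reproducible by classifying at that cutoff and recomputing the rates; this
exact round trip is an acceptance-level test.

## The synthetic cohort generator

No public gaze corpus accompanies this paradigm, so the package ships a
generator whose purpose is falsifiable testing of the pipeline, not
realism. A first-order Markov chain over
`{FAVORED, OTHER, VACANT, OFFSCREEN}` advances once per sampling step;
each state is rendered as a gaze point drawn uniformly in the matching
region, with dropout overlaid at `invalid_rate`. This is the simplest
process that reproduces the statistical structure the metrics measure:
geometric dwell runs, AOI switches, vacancy occupancy. After a block
change the chain keeps mapping FAVORED to the previous target for a
geometrically distributed lag (mean `reorient_latency_ms`, default 250 ms,
a typical reorientation latency for toddlers), so pathway adherence is
imperfect in a behaviourally plausible way.

Group presets use *lazy chains* P = (1−a)I + a·1πᵀ, whose stationary
distribution is exactly π and whose dwell lengths scale with 1/a. The
`asd_like` preset (π = 0.35/0.22/0.38/0.05 over F/O/V/S, a = 0.02,
dropout 0.12) has conditional vacancy occupancy
V/(F+O+V) = 0.40, lower favored occupancy and less AOI-to-AOI traffic than
`non_asd_like` (π = 0.68/0.153/0.147/0.02, a = 0.05, dropout 0.08,
vacancy occupancy 0.15) — effect directions matching the screening
literature (lower FAS and ASC, higher AVC in the ASD-like group), with
magnitudes that are labeled presets, not fits to any cohort.

The severity link draws an ADOS-like total score as
base + gain × group trait + Gaussian noise, rounded and truncated to the
1–10 CSS range (defaults 2.5 + 4·trait ± 1.5, putting the groups near 6.5
and 2.5, in the vicinity of reported cohort means); subscale scores add
unit noise. Severity is linked to group, not to the individual gaze
stream, so metric–severity regressions recover slope 0 under a null link
(a tested property) and group-level associations otherwise.

What the generator does *not* emulate: saccade kinematics, smooth pursuit,
pupillary light responses, calibration drift, or any spatial structure
inside a region (points are uniform). Passing tests therefore demonstrate
that the pipeline measures what it defines, under a process with known
ground truth — not that any particular clinical effect size is
reproducible.

### Sampling rate

The simulator's default is 120 Hz, the native rate of the tracker family
this paradigm uses; published protocol descriptions sometimes state other
nominal rates, so the readers never assume one: `read_gaze_table()` derives
the interval from the median inter-sample gap, and all metrics that depend
on time use that derived interval. Rate only rescales TGC/TFT; ASC, FAS−UAS
sign, and the vacancy rate are invariant to it.

## Numerical and edge-case choices

- Point-in-polygon is boundary-inclusive; polygons must be simple with
  positive area (validated by shoelace area and pairwise edge crossing).
- Timestamps must be strictly increasing; duplicate timestamps and rows
  with unparseable timestamps are dropped with a warning (a row with an
  unparseable *coordinate* is kept as an invalid sample instead — gaze
  loss, not data loss).
- Pupil averages exclude missing eyes pairwise and return `NA`, never 0,
  when no data exist. Out-of-range pupil readings (≤ 0 or ≥ 10 mm) are
  treated as missing on read.
- Zero denominators return defined values: vacancy rate 0 with no
  attended samples; empty windows count 0.
- Degenerate statistical inputs error early with the violated
  precondition named: empty groups, all-equal severity, zero slope,
  single-class truth vectors.

## Problem sizes in the shipped checks

The test suite runs every claim at the scale it needs and no larger:
conservation on 500 randomized 2-second recordings; switch-count
equivalence against a per-sample oracle on all 3¹–3¹² label sequences;
stationary-occupancy recovery on 50 000-sample chains for three
configurations, judged against the integrated-autocovariance standard
error; type-I error of the vacancy comparison on 400 replicate 15+15
cohorts; and cutoff recovery on 200 replicate 20+20 cohorts of full-length
(25 s) joint-attention recordings. These sizes give the binomial and
Monte-Carlo margins used in the assertions; they are choices of the
package, documented here so they can be scaled up by anyone re-running the
suite.

## Known limitations

- Static AOIs only; per-frame moving AOIs are out of scope.
- The dwell-time TFT overestimates fixation time when gaze sweeps through
  an AOI; use the dispersion pre-filter to probe sensitivity.
- FAS/UAS require every block to declare a favored AOI; stimuli without a
  pathway (like the speaking-face video) get ASC/AVC/TGC/TFT only, and
  the FAS fields are absent by design.
- The generator's uniform spatial emission makes pupil size and
  within-AOI position uninformative by construction; tests on those
  channels check plumbing, not biology.
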