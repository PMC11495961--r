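---
title: "Quantifying receiver startle responses from keypoint tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receiver startle responses from keypoint tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

During courtship, a bowerbird receiver stands between the bower walls
while the courting male performs discrete display elements, some of
them vigorous enough to startle the audience.  Startles are rapid,
subtle head movements that are hard to code manually but visible in
pose-estimation output: per-frame 2-D coordinates of body keypoints
(beak tip, feet, inter-tarsal joints) exported by tracking software.
`peristartle` turns such keypoint tables into a calibrated peri-event
analysis of startle magnitude, and contrasts courter status groups
(bower owners vs subordinate males) both on startle magnitude and on
the probability that a display element is followed by a bower exit.

## The relative displacement signal

The central signal is the *relative displacement* (RD): for frame
$t \ge 1$,

$$\mathrm{RD}(t) = \frac{\lVert \mathbf{beak}_t - \mathbf{beak}_{t-1}
\rVert_2}{\overline{H}},$$

where $\overline{H}$ is the bout's mean body height, itself the
per-frame absolute difference between the beak-tip $y$ and the mean
inter-tarsal-joint (ITJ) $y$, averaged over the bout.  RD is
dimensionless: RD = 0.15 is a one-frame head movement of 15% of body
size.  Normalising by body height makes bouts comparable across camera
distances; RD is invariant to translating the coordinate frame and to
jointly rescaling coordinates.

Conventions: image coordinates ($y$ grows downward), 0-based contiguous
frames per bout, 30 frames per second by default.  When both ITJ sides
are valid their $y$ values are averaged; with one side tracked, that
side is used.  The absolute value guards against recordings where the
beak sits below the ITJ in image coordinates.  RD is undefined at frame
0 and wherever the beak record is invalid in the frame or its
predecessor.

## Cleaning

Spurious detections (a branch or a bower decoration detected as a body
part) show up as implausibly fast jumps.  Per keypoint, the
frame-to-frame displacement is computed once on the raw series; records
moving more than 0.5 body heights in one frame are invalidated
("removed"), records between 0.25 and 0.5 are retained but listed
("flagged") so they can be inspected.  "Body size" here is identified
with the body height that also normalises RD — the analysis defines no
other size scale.  Design choices worth noting:

* The filter is a single pass on the raw series (default): removing a
  record does not create new candidate jumps between its neighbours.
  An iterative variant (`iterate = TRUE`) re-runs the rule on the
  surviving records until a fixed point.
* Removal invalidates the offending keypoint only, never the whole
  frame.
* The cleaning report prints the data-loss share under both natural
  denominators (frames, and frames x keypoints), because the two are
  easily conflated when comparing loss rates across studies.

A one-frame mis-detection produces two large displacements (out and
back), so it costs two removed records; a level shift costs one.  The
flagged band is machine-readable rather than a visual-inspection step,
which keeps the pipeline reproducible without a human in the loop.

## Peri-event delta statistics

For a display element starting at frame $s$ (for multi-frame "duration"
elements the start frame is the reference), with baseline length $b$
(default 10) and post length $w$:

* baseline segment: frames $s-b+1, \dots, s$;
* post segment: frames $s, \dots, s+w-1$.

The occurrence frame $s$ deliberately belongs to both segments, and
both means are taken over the full $b$ and $w$ frames including the
shared one.  The statistics are
$\Delta_{mean} = \mathrm{mean}(\mathrm{RD}_{post}) -
\mathrm{mean}(\mathrm{RD}_{baseline})$ and the analogous
$\Delta_{max}$ on segment maxima.  Baseline subtraction removes
tracking noise common to both segments and absorbs stable individual
differences in restlessness.

Under the default *strict* policy an element yields a record only when
every frame of both segments is inside the bout and has defined RD;
otherwise it is skipped with a logged reason (never a fatal error).  A
*tolerant* policy (means over defined frames, minimum coverage fraction
0.8 per segment) is available for noisier data.  Overlapping windows
from closely spaced elements are evaluated independently, one record
per element occurrence.

The group-level statistic is the unweighted mean, within a status
group, of per-male mean deltas.  Males contribute very unequal element
counts, and the average-of-averages prevents well-sampled individuals
from dominating the group value; inflating one male's element count
without changing its mean leaves the statistic untouched.

## The individual-balanced bootstrap null

The null hypothesis is that elements of the tested intensity class are
no more startling than random moments of courtship.  Each replicate
mirrors the observed statistic's construction exactly:

1. For each male, draw — uniformly with replacement from that male's
   *eligible* frames, pooled across his bouts — as many frames as the
   male contributed usable elements of the class under test.  A frame
   is eligible iff a pseudo-event starting there has full baseline and
   post segments with defined RD inside one bout.
2. Compute $\Delta$ at each sampled frame with the same window rule
   (the pseudo-occurrence frame shared by both segments), average
   within male, then average the male means unweighted.

1000 replicates (configurable) form the sampling distribution; the
2.5% and 97.5% quantiles give the significance band and the empirical
p-value uses the add-one form
$p_{up} = (1 + \#\{\Delta^\ast \ge \Delta_{obs}\})/(B+1)$, two-sided
$p = \min(1, 2\min(p_{up}, p_{lo}))$.  The two-sided convention matches
the reporting of both elevated responses (startles) and significantly
below-average movement (freezing).  By default the number of sampled
frames per male equals the count of elements of the class under test
(so the low-intensity control uses low-intensity counts).

For tiny datasets an *exhaustive* mode replaces Monte-Carlo sampling by
full enumeration: all per-male frame multisets, weighted by their iid
sampling probability (multinomial coefficient over $n^k$), combined
across males.  The enumerated values coincide with the unordered
multiset means, while the weights reproduce the sampling law, so
exhaustive and Monte-Carlo modes agree in the large-$B$ limit; the test
suite checks both properties against brute-force enumeration.

### Robustness sweeps

Because bowerbird startle latencies are unknown (the only comparative
anchor is a 50-100 ms range measured in starlings), no single window
can be privileged.  The sweep recomputes estimate, band and p-value for
post sizes 4-50 frames (133-1667 ms at 30 fps) at fixed baseline 10,
and again for baselines 5, 10, 15 and 20.  Each grid cell's null is
resampled with a seed derived deterministically from the master seed
and the cell index, so any single cell can be reproduced in isolation.
Leave-one-out stability re-runs the test omitting one male at a time;
here the *same* seed is reused across omissions so that omitting
interchangeable males yields identical rows — a deliberate exception to
per-cell seed derivation, trading independence of rows for exact
symmetry.

No multiple-testing correction is applied across the sweep grid; the
output flags raw per-cell significance, and neighbouring cells are
strongly dependent (they share the data and most of each window).

## Bower exits and annotation agreement

An exit is attributed to the most recent element whose start frame
precedes it within the same bout (no maximum lag by default; a lag cap
is configurable).  An element's outcome is 1 iff at least one exit is
attributed to it.  The status contrast is tested, by default, with a
cluster permutation test: the statistic is the difference between
status groups in the unweighted mean of per-male exit proportions, and
the null permutes status labels across males — males, not elements, are
the exchangeable units, which respects the repeated-measures structure
without distributional assumptions.  With few males the permutation
distribution is enumerated exhaustively and the p-value is exact.  A
binomial GLMM (status as fixed effect, random intercepts for male and
date, likelihood-ratio test) is provided as an alternative contract;
it is standard machinery rather than part of this package's
contribution, and the permutation default is preferred because it is
exactly testable against enumeration.

The validation helper compares automatic and manual annotations on
shared (bout, frame, keypoint) keys and reports per-keypoint Euclidean
error (pixels and body-height fractions, the latter exactly pixel error
divided by the bout's mean height) plus per-axis correlations — a
superset of common validation summaries, since no single convention is
universal.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` generate datasets with the
statistical structure the analysis assumes, so every stage is testable
without field data.  A bout is a static pose (the receiver standing
still, as the inclusion criteria for 2-D tracking require) plus:

* per-frame Gaussian keypoint jitter (default sd 1% of body height per
  axis — sub-pixel to a-few-pixel tracking noise at typical scales);
* rare single-frame mis-detections (default rate 0.001 per frame per
  keypoint, magnitudes 0.2-0.8 body heights, deliberately straddling
  the flagging and removal thresholds);
* a renewal stream of non-overlapping display elements (exponential
  gaps plus a 25-frame minimum, so peri-event windows rarely — but can
  — overlap), 40% high-intensity with durations 36.69 +/- 35.92 frames
  (truncated at 2), the rest low-intensity split between 1-frame
  "event" and short "duration" kinds;
* a startle pulse for each high-intensity element (probability 1 by
  default): the beak traverses a closed polygon with one side of
  `startle_magnitude` body heights per frame, for
  `startle_duration_frames` frames (default 3), beginning a uniform
  1-3-frame latency after the element onset.  The pulse touches the
  beak only, since RD is beak-based.  Default magnitudes are 0.3 body
  heights for owners and 0 for subordinates — the status contrast the
  pipeline is designed to detect;
* optional bower exits following high-intensity elements with
  per-status probability (default 0.2 for both statuses, reflecting a
  null status effect on exits).

Counts mirror the recording design: 9 owners and 8 subordinates, 4-32
bouts per male, bouts of 300-1000 frames at 30 fps.  Where the
emulated design fixes no value (jitter, mis-detection rate, element
rate, exit rate, latency), defaults were chosen once as field-realistic
and are documented above; they are conditions of the simulation, not
tuning knobs.

The closed-polygon pulse makes the injected effect analytically
tractable: with pulse magnitude $M$, jitter sd $j$, per-axis
displacement-noise sd $s = j\sqrt{2}$, the expected per-event
$\Delta_{mean}$ is

$$E[\Delta_{mean}] = \frac{\overline{o}}{w}\Big(M + \frac{s^2}{2M} -
s\sqrt{\pi/2}\Big),$$

where $\overline{o}$ is the mean overlap (over latencies) between the
pulse and the post window, $s\sqrt{\pi/2}$ is the Rayleigh mean of
jitter-only RD displaced by the pulse frames, and $s^2/(2M)$ is the
second-order noise correction to the pulse magnitude.  The test suite
verifies recovered deltas against this closed form.

What the generator does *not* emulate: pose-detector error structure
beyond jitter and jump mis-detections (no occlusion runs, no
keypoint-specific bias), receiver locomotion or posture change, element
sequencing structure, or any courter movement.  Passing tests therefore
certify the statistical machinery under the stated generative
assumptions, not the behaviour of the detector on real video.

## Numerical choices

* Delta computation over all frames uses cumulative sums with explicit
  undefined-frame accounting; per-event records equal a naive
  double-loop recomputation exactly on fixtures, which the suite
  asserts.
* $\Delta_{max}$ rolling maxima use `zoo::rollapply`; undefined frames
  propagate, matching the strict policy.
* Quantiles of Monte-Carlo nulls use R's default (type 7) sample
  quantiles; exhaustive mode uses weighted quantiles (smallest value
  whose cumulative weight reaches the probability).
* Degenerate inputs fail loudly and specifically: zero mean body
  height, missing ITJ, empty status groups, windows larger than every
  bout (empty eligibility with a warning), groups of one male for
  leave-one-out.
* All randomness flows from explicit seeds; the same seed gives
  byte-identical simulations and replicate vectors.  Derived per-cell
  seeds stay below $2^{31}$.

## Problem sizes used by the test suite

The suite exercises the pipeline at deliberately reduced scale so that
a full run stays interactive: calibration uses 500 simulated
no-startle datasets of 4 males x 6-8 bouts x 400-600 frames with
B = 200 bootstrap replicates; power and recovery use 100 datasets of 3
males with the 0.3-body-height pulse; the sweep-shape check uses one
10-male dataset across post sizes 4-50.  Bout counts and lengths sit
inside the emulated recording design's ranges because the bootstrap's
conditional null needs a reasonably rich eligible-frame pool per male:
at much shorter bouts (a few hundred frames) the test over-rejects
mildly (about 6% instead of 5% at the smallest sizes we measured), a
finite-sample effect worth keeping in mind for very small field
datasets.

## Known limitations

* RD is 2-D; depth movement is invisible, which is why the analysis
  assumes receivers stationary on the camera axis.
* The per-frame RD of pure jitter has a positive mean (Rayleigh), so
  absolute RD levels reflect tracking noise; only baseline-corrected
  deltas are interpreted.
* The bootstrap null treats frames within a male as exchangeable;
  slow within-bout trends in restlessness would violate this and are
  not modelled.
* Exit attribution ("followed by") uses the most recent preceding
  element with no lag cap by default; analyses sensitive to the lag
  definition should set `max_lag` explicitly.
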