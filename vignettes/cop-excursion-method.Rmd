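---
title: "Measuring center-of-pressure excursion on a pressure-sensitive mat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring center-of-pressure excursion on a pressure-sensitive mat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copmat)
```

## The measurement problem

A pressure-sensitive walkway samples a rectangular grid of on/off (or
graded) pressure cells at a fixed rate. During barefoot walking each foot
contact activates a patch of cells that grows from the heel forward and
releases from the heel forward as the foot rolls over. The center of
pressure (COP) at any instant is the centroid of the vertical pressure
distribution; its excursion over one stance phase carries information
about balance, foot function and gait performance. `copmat` implements
the complete path from raw cell activations to per-footfall COP
parameters, plus the statistics needed to judge how many footfalls must
be averaged before those parameters are reliable.

The defaults throughout the package describe the hardware and cohort the
method was developed on: 240 Hz sampling, 12.7 mm cell pitch, a
3.66 m x 0.61 m active area, and healthy young adults walking at a
comfortable (about 129 cm/s) or fast (about 162 cm/s) pace.

## Footfall geometry

Footfalls are maximal sets of cell activations connected in space
(8-connectivity) and contiguous in time (gaps of at most `max_gap = 2`
frames, so a single flickering sensor does not split a contact). Clusters
below `min_cells = 5` cells are treated as noise. Sides are assigned from
the sign of each footfall centroid's lateral offset to the least-squares
midline of progression; a sequence that does not alternate left/right is
flagged `unknown` rather than guessed, because a mislabeled side silently
mirrors the mediolateral axis.

The foot axis is the line `l` from the heel center `H` to the toe center
`T`, defined as the area centroids of the proximal and distal thirds of
the contact. Thirds and axis depend on each other, so the estimate is
bootstrapped: the principal axis of the cell centers (oriented toward the
walking direction) gives provisional thirds, whose centroids give a
provisional `l`; one refinement pass recomputes thirds and centroids
along that line. One pass suffices because the provisional axis of a
foot-shaped cluster is already within a few degrees of the final one; the
refinement mainly stabilizes the third boundaries. Thirds split the
extent of the cell-center projections into three equal intervals, with
boundary ties going to the more proximal interval (a deterministic
tie-break matters because event detection reads thirds directly).

COP samples are moved into the foot frame by translating `H` to the
origin and rotating through `theta_c = atan2(c - e, d - f)` (for
`T = (c, d)`, `H = (e, f)`), the sign convention under which `T` lands on
the positive y-axis exactly. For left feet the x-axis is mirrored
afterwards, so `+x` is always medial-to-lateral and left/right
trajectories superimpose. Foot length and width are the cell-center
extents along and across `l` plus one cell pitch, because centers
understate the physical outline by half a cell at each end.

## Stance events and parameters

Six events are read off the per-cell first-activation and
last-deactivation times (a cell may flicker; first-on/last-off is used):
first contact, midfoot-on (first middle-third activation), foot-flat
(78% of the footfall's cells activated), heel-off (last proximal-third
deactivation), midfoot-off (last middle-third deactivation) and last
contact. The 78% count is cumulative over distinct cells with a ceiling
threshold — "have been activated" reads most naturally as a cumulative
count and a ceiling avoids fractional cells; a concurrent-count variant
is available via `fft_rule = "concurrent"` for sensitivity analyses.
Events are reported at frame resolution with no sub-frame interpolation:
the device genuinely samples at 240 Hz and interpolated event times would
suggest more precision than the hardware has. Footfalls whose events are
not monotone are excluded and logged, never repaired, mirroring the
practice of discarding visibly abnormal trials.

The five subphases (ICP, LCP, FFP, IPP, LPP) tile the stance exactly;
CbP merges LCP and FFP because the foot-flat event that separates them is
by far the most variable event. Per subphase the package reports the
duration as % of stance, displacement ranges (mm) and mean locations
(signed, % of foot width/length — the COP starts behind the heel center,
so anteroposterior means in ICP are negative), and velocities in cm/s.
Velocity is path length over duration (summed absolute increments, or the
Euclidean path for the total velocity), not net displacement over
duration: published velocity magnitudes are only attainable with the
path-based reading, and a net-displacement variant stays available via
`velocity_def = "net"`. An increment between two consecutive samples is
attributed to the subphase containing the later sample, so adjacent
subphases share boundary samples without double-counting increments.
Empty subphases (two events can coincide at frame resolution) yield `NA`,
never a fabricated zero.

`resample_trajectory()` linearly interpolates a trajectory at 100 equally
spaced stance percentages, optionally normalized by foot width and
length, which is the form used to average trajectories across a cohort.
Parameters themselves are normalized per subject; cohort-average
normalization is left to the plotting path, where a common scale is what
makes a mean band meaningful.

## Arch index

The arch index of a static, toe-excluded footprint is `b / (a + b + c)`,
the middle third's share of the contact area along the footprint's own
length. Cell areas are apportioned to the three intervals by fractional
overlap, so a uniform rectangle yields exactly 1/3 regardless of how many
rows it spans. Toes are removed by mask when available, otherwise by a
conservative heuristic (detached components beyond the most distal empty
cross-section row), which refuses to act when it would delete more than
40% of the footprint. Classification thresholds default to the
conventional 0.21/0.26 bands (below = high arch, above = flat foot) and
are configurable, since published cohorts rarely state their exact
cut-offs.

## Reliability suite

For one parameter, one condition and the dominant foot, the first `k`
complete footfalls of each subject form an n x k matrix (incomplete
subjects are dropped: the unreplicated two-way ANOVA needs a full
matrix and no imputation rule would be defensible). From the ANOVA mean
squares:

* `ICC(2,1)` — two-way random effects, absolute agreement, single
  measurement — with the F-based confidence interval of the
  McGraw-Wong convention and an F test of ICC > 0 (flagged at
  alpha < 0.001);
* `ICC(2,k)`, algebraically identical to the Spearman-Brown prophecy of
  ICC(2,1) at the same k (the package tests this identity to 1e-12);
* the column F test for systematic bias across repetitions;
* within-subject CV (mean over subjects of per-subject CV; a pooled
  variant exists), reported for both feet but not for signed
  mean-location parameters, whose near-zero means make CV meaningless;
* `SEM = SD * sqrt(1 - ICC(2,k))` with SD the between-subject SD of the
  k-footfall means — the error of the averaged measurement, which is the
  quantity a study reports;
* `MDC = SEM * sqrt(2) * z` with `z = 1.64` (90% confidence; the
  sqrt(2) carries the uncertainty of comparing two measurements);
* `required_k`, the ceiling of the inverted prophecy at a target
  reliability of 0.50 — whole footfalls, because one collects whole
  footfalls.

`sample_size_icc()` provides the Fisher-transform approximation for
planning: with a minimally acceptable reliability of 0.5, an expected
0.6, one-tailed alpha 0.05, power 0.80 and 16 repetitions it returns 91
subjects. It is advisory; the approximation and the rounding convention
differ between published variants by a subject or two.

## The synthetic generator

`generate_footfall()` rasterizes a foot-shaped outline (piecewise-linear
half-width profile: blunt heel, narrower arch, wide forefoot, tapering
toes) onto the mat at a given position and orientation, then assigns each
cell continuous activation/deactivation times from a heel-to-toe contact
wave. The wave is calibrated so the realized stance events land at
requested percentages of stance; cohort distributions for foot size,
pace, stance duration and event percentages (with separate
between-subject and within-footfall components) reproduce the reference
scales for healthy young adults. Ground-truth events are computed from
the continuous times with the same third-partition and event rules the
detector applies, and ground-truth parameters from a 1 ms sampling of the
continuous COP model, so the only expected measurement error is the
240 Hz / 12.7 mm discretization.

Several design choices exist purely to make that discretization error
small and analyzable rather than to imitate physiology:

* the contact wave advances one cross-band (one pitch) at a time, so the
  sub-frame lateral fill-in of a band cannot alias the mediolateral path;
* per-cell base weights are centered laterally within each band, so the
  planted mediolateral excursion comes from a smooth sway modulation of
  the pressure field, not from raster jaggedness of the outline;
* the heel lands, and the toes release, as patches with identical
  timing, giving the COP well-defined stationary limits at both ends of
  stance;
* the whole pressure field evolves on a "rollover clock" that runs at
  half speed in a window around each realized event, so event snapping
  at frame resolution cannot misattribute large COP movements across a
  subphase boundary;
* per-cell pressure rises and falls as a half-sine that vanishes
  continuously at activation and deactivation, keeping the continuous
  COP free of jumps;
* footfall contact times are drawn asynchronously with the sampling
  clock, as in reality — phase-locking them would bias the first-contact
  snapping.

What the generator does **not** model: medial arch asymmetry between the
foot's two borders, pressure magnitudes in physical units, double-support
interaction between feet, pathological rollover patterns, sensor
hysteresis or crosstalk. Passing recovery tests on this generator
therefore demonstrates that the pipeline inverts the stated contact-wave
model at hardware resolution — not that it is robust to every real-world
artifact. The mediolateral velocity scale of the synthetic data in the
foot-flat phase is, in particular, smaller than in real cohorts, where
footfall-to-footfall variability dominates.

Recovery tolerances follow the hardware: events to one frame (about
4.17 ms), spatial parameters to one cell pitch (12.7 mm). Velocities are
compared on footfall means pooled over subjects, the statistic a
reliability table reports; per-footfall velocities on a 30-80 ms subphase
inherit the full ±1-frame duration uncertainty (up to ~10% by
themselves), which no estimator reading events at frame resolution can
avoid.

## Numerical choices and degenerate inputs

* Third-boundary ties go proximal; an exactly-at-boundary COP sample
  belongs to both adjacent subphases' sample sets, while increments
  follow the later sample.
* Residual mean squares at rounding-noise level (relative 1e-12) are
  treated as exactly zero, so perfect-agreement matrices give ICC = 1
  and a missing F rather than numerical garbage.
* `required_k` guards the ceiling against floating-point overshoot at
  exact integers.
* Degenerate footfalls (< 3 cells, no spatial extent, an empty proximal
  or distal third) raise errors naming the footfall; empty recordings
  produce empty, fully-typed tables.
* Reliability matrices need at least 2 subjects and 2 repetitions; rows
  with any missing value are dropped beforehand.

## Problem sizes used by the test-suite

The packaged tests run the full pipeline on cohorts of up to six
synthetic subjects with five footfalls per pass, a sixteen-step single
recording on an extended virtual mat, and 1000-replicate Monte-Carlo runs
of the ICC estimator at the n = 90, k = 7 design point — sizes chosen so
the whole suite completes in well under a minute while still exercising
the cohort-level statistics at the study's own design numbers.

## Known limitations

Partial footfalls at the mat edge are detected like any cluster but will
usually fail validation (missing thirds or non-monotone events) and be
excluded rather than flagged as "partial" specifically. Between-session
(test-retest) and inter-rater reliability, Bland-Altman analysis,
pressure-time integrals and regional loading are out of scope. The side
assignment assumes roughly straight walking; strongly curved paths will
produce `unknown` sides.
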