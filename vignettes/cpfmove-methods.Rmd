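---
title: "Methods: movement metrics for central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement metrics for central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfmove)
```

`cpfmove` measures how central-place foragers use the landscape around a
home base from per-person-day GPS tracks. This vignette documents the
processing model, the metrics, the numerical conventions, the synthetic
data generator, and what the package's tests do and do not establish
about real field data.

## The unit of analysis

Everything is computed on the *person-day*: one individual's ordered fix
sequence for one local calendar day. Local days are assigned under a
fixed UTC offset (default +3, East Africa Time, configurable), and
recordings that span local midnight are split at midnight with a flag —
a convention of this package, chosen because every downstream metric is
daily. Duplicate timestamps keep the first fix; both choices are
deterministic and order-preserving.

## Preprocessing chain

1. **Projection.** Tracks are projected to a camp-centred planar frame
   by a local equirectangular projection (x = R·Δλ·cos φ₀, y = R·Δφ,
   R = 6,371,008.8 m) about the camp polygon's area centroid. Against
   the haversine distance the planar error is below 0.1% for pairs
   within ~20 km, which covers daily foraging ranges; points beyond
   200 km are refused. The projection was chosen for closed-form
   invertibility (the simulator uses the inverse) and testability.
2. **Speed filtering.** Spatially errant fixes are removed in two
   passes. A fix whose implied speed from *both* neighbours exceeds a
   hard ceiling (default 20 km/h, a generous pedestrian bound) is
   removed, iterating to a fixed point — a single teleported fix
   implies impossible speeds on both sides, while its honest
   neighbours do not. Then fixes faster than 10× the *modal moving
   speed* from both neighbours are removed; the mode is the midpoint of
   the most populated 0.1 m/s bin among fixes moving at ≥ 0.3 m/s.
   Restricting the mode to moving fixes matters: the raw modal speed of
   a camp day is the stationary noise bin near zero, and a multiplier
   on it would shred genuine walking. Removing more than 10% of a track
   warns; more than 50% marks the track unusable.
3. **Vehicle days.** A person-day with sustained travel above 3.5 m/s
   for longer than 120 s is dropped wholesale, so analysed days are
   pedestrian only. The duration guard keeps short running bursts.
4. **Resampling.** Positions are linearly interpolated onto an even 5 s
   grid from the first to at most the last recorded instant (no
   extrapolation). Interpolation is idempotent on the grid and can only
   shorten a path (triangle inequality) — both properties are tested.
   Recording gaps longer than 300 s are bridged but flagged
   `gap_filled`: bridged spans count toward daily distance (distance is
   defined over *all* travel) but are excluded from sinuosity, where a
   straight bridge would bias the ratio toward 1.
5. **In/out of camp.** Even-odd point-in-polygon against the camp
   boundary; boundary fixes count as in camp.
6. **Inclusion.** Only person-days whose recorded span (last minus
   first timestamp, not fix count) reaches 8 h are analysed, so
   comparisons cover the normally active hours of the day. The boundary
   is inclusive: a 8.00 h track is in.

## Land visitation

A raster of square cells (default 10 m × 10 m, area A = 100 m²) is
anchored at the camp centroid; cells are half-open so every point
belongs to exactly one cell. The cells a track visits are computed by
*supercover* rasterisation: for each consecutive fix pair, every cell
whose closed square the segment intersects, including corner touches —
"cells the track intersected" read as geometric intersection, and the
corner convention keeps cell sets stable under path reversal. Then

- daily land visited = (unique cells that day) × A,
- cumulative land explored through day *i* = (unique cells over days
  1…*i*) × A, non-decreasing and bounded by the summed daily visits,
- gender segregation per camp: unions of male and female cell sets and
  their intersection (land visited by at least one man and one woman);
  conservation (male-only + female-only + both = total) is exact in
  cell counts because areas are reported from counts, not polygonised
  outlines. Camps lacking tracks of either gender are excluded.

Grid alignment is not part of the metric's definition, so absolute
areas depend weakly on the anchor; for day-scale tracks the variation
under sub-cell origin jitter is far below other error sources, and
anchoring at the camp centroid makes results reproducible given camp
and data.

Home ranges use the conventional minimum convex polygon: discard the
⌈(1−f)·n⌉ fixes farthest from the points' centroid (f = 0.95 by
default) and take the convex hull of the rest. Collinear degenerate
hulls report zero area with a warning.

## Sinuosity

Sinuosity is the ratio of distance travelled to the straight-line
distance between the endpoints, ≥ 1 by the triangle inequality. The
day's *principal bout* is the maximal out-of-camp run, extended to the
bracketing in-camp fixes so chords are camp-anchored, that reaches at
least 500 m from the camp centroid; if several qualify, the one with
the greatest path length. It is split at its apex — the fix farthest
from the camp centroid, ties to the earliest fix (deterministic, and it
favours the longer inbound segment). Outbound and inbound sinuosity are
each segment's path length over its chord. Chords shorter than 1 m
(loops) are undefined and logged rather than divided by.

*Geographically weighted* sinuosity asks over how many distinct places
sinuous travel happened, distinguishing many turns in one spot from
turns spread across the landscape. Out-of-camp travel is segmented by
the raster: a *pass* is a maximal stretch of travel inside one cell,
extended to the exact boundary-crossing points where the path enters
and leaves; its sinuosity is in-cell path length over the entry–exit
chord (dwell-only passes with chord < 1 m are skipped), and a cell's
value for a track is the mean over that track's passes. This
entry/exit-chord construction is this package's resolution of the
otherwise underspecified "sinuosity of travel crossing a cell": it is
local, deterministic, and reduces to exactly 1 for straight crossings.
Population statistics — the mean and 99th percentile over all cell
values of all tracks in a run — are computed once and cached; a track's
cell counts as *high* if strictly above the mean and *very high* if
strictly above the percentile (strict inequalities, so an all-equal
population scores nothing high).

## Sociality

From each person-day, up to 100 out-of-camp fixes are drawn uniformly
without replacement (all of them if fewer exist). For each sampled fix,
every other tracked individual contributes the fix of theirs temporally
closest to the sample instant if it is within ±60 s — actual GPS
measures, deliberately not interpolated positions; the
nearest-neighbour distance is the minimum over individuals (of either
gender) and `n_concurrent` counts the contributors. "Within 5 m" is
decided inclusively (≤ 5.0 m, tested at the 3-4-5 boundary). The
empirical probability of being within 5 m is reported per gender in
distance-from-camp bins with binomial standard errors √(p(1−p)/n) — a
descriptive companion to the smooth mixed-model fits such tables feed.

## Summary statistics

Camp-by-gender tables append an unweighted cross-camp mean row: plain
column means, except that the ratio column is the mean of per-camp
male:female ratios and the overlap percentage is recomputed as
100 × mean(both)/mean(total) — the ratio-of-means convention
reproduces published camp summaries exactly, whereas the mean of
percentages differs in the last decimal. The Wilcoxon signed-rank test
is exact: V is the rank sum of positive differences (average ranks for
ties, zeros dropped) and the two-sided p enumerates the null by
convolution over sign assignments — appropriate because camp-level
samples are small (n ≤ 25 enforced). Cohen's d uses the pooled-SD
definition with a seeded percentile bootstrap CI.

## The synthetic generator

Field GPS data of this kind are access-restricted, so the package ships
a generator whose defaults encode the study conditions the pipeline is
meant for, and whose knobs map one-to-one onto the measured contrasts:

- A person-day is hearth dwell → one out-and-back foray → apex dwell →
  return → hearth dwell, recorded at 5 s for ~11.5 h (the device-worn
  span), starting near 07:45 local.
- The foray is a biased random walk: each step of length speed × 5 s
  (speed 1.25 m/s) has heading drawn von Mises around the bearing to
  the goal with concentration κ. The expected per-step progress is
  A(κ) = I₁(κ)/I₀(κ), so expected sinuosity is 1/A(κ) — the closed
  form used to spend a planned walking budget L ~ N(μ, (0.18 μ)²) by
  placing the apex at distance D = L·A(κ)/2. Realized noiseless day
  range therefore tracks the configured mean, and the manifest records
  it as ground truth for recovery tests.
- Default profiles: men 14 km/day at κ = 1.5 (expected sinuosity
  ≈ 1.7), solitary; women 8 km/day at κ = 4 (≈ 1.2), in parties of
  four. Party members share one planned path plus a smooth AR(1)
  offset (SD 2 m) that evolves only while moving — the party sits
  together at dwells; member spacing then has a ~3 m median, and the
  within-5 m probability lands near 0.8–0.9.
- GPS error is AR(1) per axis with SD 1 m and lag-5 s correlation
  0.998: receiver error drifts over tens of minutes rather than
  jumping fix to fix. This matters because distance is summed over
  fixes: white noise of realistic amplitude would add tens of
  kilometres of jitter to a stationary day, which no receiver shows.
  Errant fixes (uniform in a 5 km disc, rate 5 × 10⁻⁵ per fix)
  exercise the speed filter; an optional 10-minute 8 m/s segment
  exercises vehicle-day exclusion; an optional adaptive-logging mode
  thins stationary spans to one fix per 15 s to exercise resampling.
- Each person-day draws its RNG substream from a stable hash of
  (seed, date, party), so any track is reproducible in isolation and
  results are invariant to generation order.

What the generator does *not* emulate: terrain, vegetation and
resource-driven route choice, hunting pursuit dynamics, multi-foray
days, heavy-tailed step lengths, canopy-dependent GPS quality, or
social structure beyond fixed-size parties. Passing recovery tests
therefore show the *pipeline* measures what it claims on data with
known truth — not that real foraging data satisfy the generator's
assumptions.

## Problem sizes and verification

The end-to-end checks run a camp of 10 individuals per gender for 5
days (100 person-days of ~8,000 fixes each, about half a minute of
computation) and verify: the day-range ratio recovers the configured
14:8 within 10%; male mean cumulative land exceeds female at every day
index ≥ 2; measured sinuosity is ordered by κ (levels 1, 5, 20, 100
and the gendered contrast); within-5 m probability for party foragers
is at least the solitary value in every occupied distance bin; and
Cohen's d of measured daily distance is within 0.15 of the value on
the generator's ground truth. Geometry primitives are tested against
independent oracles: supercover against 1 cm segment sampling plus
exact segment–square clipping for sub-resolution corner grazes;
per-cell passes against a dense-resampling reimplementation; the
planar projection against the haversine; the exact Wilcoxon against
both direct sign-pattern enumeration and `stats::wilcox.test`.

## Known limitations

- Absolute raster areas depend (weakly) on grid anchoring; compare
  areas only within a common camp grid.
- The pass-based cell sinuosity is one defensible reading of
  "sinuosity of travel through a cell"; alternatives (e.g. windowed
  path sinuosity attributed to cells) would differ in detail.
- Daily distance includes residual GPS jitter; with slowly drifting
  receiver error this is small, but fast white-noise receivers would
  inflate it, and no smoothing step is applied.
- The exact signed-rank enumeration is limited to n ≤ 25 pairs by
  design; larger samples should use a normal approximation, which the
  package deliberately omits.
- Statistical modelling of the exported tables (hierarchical additive
  models of distance, exploration, sinuosity or proximity) is out of
  scope; `export_model_tables()` produces the tidy inputs.
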