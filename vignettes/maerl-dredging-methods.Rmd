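---
title: "Quantifying dredging impacts on maerl beds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dredging impacts on maerl beds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maerlspi)
```

## The problem

Maerl (rhodolith) beds are three-dimensional biogenic habitats built by
free-living coralline algae. Clam dredging breaks and buries thalli, compacts
the substratum and smooths the bed surface. `maerlspi` implements a
quantitative chain linking dredging pressure to bed structure:

1. **AIS pings to a pressure raster.** Vessel positions and speeds become
   dredging segments, segments become per-cell swept area, and multi-season
   cumulation yields a dimensionless dredging intensity per 50 m cell.
2. **Sediment profile imagery (SPI) to structure metrics.** In-situ
   cross-section images of the bed, with a manually traced water--maerl
   interface, yield interface rugosity, prism penetration depth, live/dead
   area ratio and interface-flattened vertical class profiles.
3. **Thallus silhouettes to shape descriptors.** Mean perimeter and the
   solidity index (area over convex area) summarize thallus size and
   branching complexity.
4. **Permutation statistics.** One-way PERMANOVA with pairwise pseudo-t
   tests, PERMDISP dispersion tests, and a small family of pressure--response
   regressions.

Because the original field data are not deposited, a synthetic-data generator
is a first-class module: it emulates all four input streams with exact ground
truth, which is what the test suite and the acceptance script run against.

## Dredging pressure model

A vessel is dredging when its speed over ground lies in the fleet's typical
fishing window, 2.5--5 knots (inclusive). Maximal runs of at least two
consecutive in-window pings of one vessel within one season form a segment
whose polyline joins ping positions with straight chords; a single isolated
in-window ping carries no length and is discarded. Chord geometry is a
convention justified by high-frequency pings — no speed-based interpolation
is attempted, and a run may span arbitrary time gaps (the data carry no
explicit event delimiters).

Each chord is clipped analytically against the half-open 50 m cell lattice
(crossing parameters of the lattice lines are solved exactly; each piece is
attributed by its midpoint, so points on shared edges belong to the
higher-index cell). Swept area in a cell is clipped length times the 1.5 m
dredge width; summing over cells returns exactly length times width
(conservation). Pressure is swept area cumulated over the season set divided
by the 2500 m^2 cell area — "times the cell has been fully dredged" — and can
exceed 1.

Stations are discretized into `Control`, `Moderate` and `High` groups with
thresholds 0.1 and 2.0, chosen inside the gaps of the observed group ranges
(0--0.06, 0.61--1.56, 2.52--3.26); both thresholds are arguments.

```{r pressure-example}
grid <- define_grid(c(0, 0), 50, 2, 2)
tracks <- generate_ais_tracks(
  make_pass(1, "V1", "2016-2017", speed_kn = 3.5, from = c(0, 25),
            to = c(50, 25)), grid)
segs <- detect_dredging_segments(tracks$pings)
cumulate_pressure(rasterize_swept_area(segs, grid), grid)
```

## SPI classification and metrics

Pixels above the traced interface are never analyzed. Below it,
classification is two-staged: a pixel darker than `dark_threshold`
(channel-mean brightness, default 95/255) is interstitial space — shadowed
voids or sediment between branches — and the remaining pale maerl pixels are
split by a single red-channel threshold (default 185/255): pigmented live
thalli above, bleached dead thalli below. The brightness-first rule is this
package's resolution of an underdetermined verbal description ("RGB color
composition"); interstices are dark while both maerl classes are pale, so
brightness separates maerl from background before the red channel separates
live from dead. Both thresholds are arguments, and
`calibrate_red_threshold()` fits the red threshold on labelled pixels by
minimizing misclassification, mirroring the expert-agreement calibration used
in practice.

Conventions: the image origin is top-left, rows increase downward, and a
trace value is the number of water rows in that column (0-based interface
row). Metrics follow closed formulas:

* **Rugosity** = sum of absolute between-column interface differences divided
  by the full width in pixels (not width − 1, following the source
  definition); translation-invariant.
* **Penetration depth** = (height − mean interface row) × pixel size.
* **Live/dead ratio** = live area / dead area; images with no dead pixels are
  flagged undefined and excluded from station aggregates (clamping them would
  inject infinities into station SDs), with the exclusion count logged.
* **Vertical profiles**: each column is shifted so its interface sits at
  depth 0; pixel depth is taken at the pixel's top edge and binned into
  half-open 5 mm bins. Percentages are of each bin's own pixels (the only
  normalization under which the three classes are comparable across depths);
  empty bins are flagged missing rather than zero-filled. The deepest bins
  may be ragged where columns run out of image.

## Thallus morphometrics

Silhouettes are thresholded on brightness, labelled with 8-connected
components (diagonally touching labels are merged on top of the 4-connected
labelling the image library provides), debris below `min_area_px` is
dropped, and holes are filled before measurement — the solidity index is
defined on the silhouette area.

Perimeter is estimated on the outer boundary chain with calibrated step
weights (0.980 straight, 1.406 diagonal, −0.091 per direction change) plus a
half-pixel boundary-offset term of $\pi$. The calibrated weights remove the
systematic overestimation of a naive $(1, \sqrt2)$ chain on slanted
boundaries, and the offset accounts for the chain running through pixel
centers half a pixel inside the true silhouette edge; jointly they keep a
10 px square within 5% of its true perimeter 40 and digital disks within
about 1--3% of $2\pi r$. A plain $(1,\sqrt2)$ chain fails the square case by
−10%, which is why the calibrated form is used.

Solidity divides the filled pixel count by the area of the convex hull of the
boundary-pixel *corners* (not centers), so convex silhouettes score exactly 1
and a plus-sign of five unit squares scores exactly $5/7$ at any resolution
where the rasterization is faithful. Station summaries pool all thalli over a
station's cores in a single stage; the original per-core structure is kept in
the per-thallus table for users who prefer two-stage averaging.

## Permutation statistics

The one-way pseudo-F partitions the squared Euclidean distance matrix:
$SS_{total} = \sum_{i<j} d_{ij}^2 / N$, within-group sums are computed per
group with its own $n_g$, and
$F = (SS_{among}/(a-1)) / (SS_{within}/(N-a))$. For univariate responses this
is exactly the classical ANOVA F (asserted to 1e-10 in the tests, and
cross-checked against an independent PERMANOVA implementation for
multivariate responses).

Significance uses unrestricted permutation of observations. When the number
of distinct group assignments is at most 10,000 the set is enumerated
exhaustively and $p = \#\{F_{perm} \ge F_{obs}\}/\#\text{arrangements}$ (the
identity is part of the enumeration); otherwise 9,999 random permutations are
drawn by default and $p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(B + 1)$, which
keeps $p \ge 1/(B+1)$. Pairwise comparisons report the pseudo-t (square root
of the two-group pseudo-F), uncorrected by default to match conventional
reporting, with a Bonferroni option. Numerical ties in the permutation
distribution are counted as exceedances with a relative tolerance of 1e-12;
a perfectly separated grouping yields an infinite pseudo-F, which is retained
and compared without tolerance. When all observations are identical the
partition is empty and the test reports F = 0, p = 1, flagged degenerate.

PERMDISP computes each observation's Euclidean distance to its **group
centroid** (responses here live in Euclidean space, so centroids rather than
spatial medians are the natural choice), then applies the one-way pseudo-F to
those distances with significance by permuting the distance values across
groups. Because the centroids are estimated from the same observations, the
test is known to run slightly liberal for very small groups (we measure
about 9% rejection at nominal 5% with groups of 6, and nominal behaviour by
groups of 10); analyses with few replicates should read marginal PERMDISP
p-values accordingly. Profile matrices are normalized before multivariate
tests — each depth-bin variable centred and scaled to unit SD across
stations, zero-variance bins dropped with a warning.

Both the main tests and the dispersion tests are always reported side by
side; whether a significant main effect should be read conditionally on a
dispersion effect is left to the analyst, as the conventional tabulation
does.

## Pressure-response regression families

Four least-squares families describe station metrics against pressure:
exponential decay $a e^{-bx} + c$, exponential-plus-linear
$a e^{-bx} + dx + c$, cubic polynomial, and linear. Nonlinear members are
fitted by Levenberg--Marquardt from data-driven starts ($c$ just below the
minimum response, $a$ the response range, $b$ from a log-linear slope) with
five jittered restarts under a fixed seed; if no start converges the failure
is reported with diagnostics. Families are compared on the small-sample
corrected AIC. Two numerical choices matter:

* RSS is floored at the squared numerical precision of the response before
  entering the AICc, so families that fit noiseless data exactly are ranked
  by parsimony instead of by rounding noise.
* A decay term whose span over the observed pressure range is below 1e-6 of
  the response range is flagged degenerate (the curve has collapsed to an
  intercept).

## The synthetic-data generator

The generator is the package's ground-truth instrument, emulating the study
conditions: 30 stations × 15 SPI frames (450 images) across a pressure
gradient from 0 to 3.26 in three clusters matching the observed group ranges;
frames of 725 × 1090 px at 0.02 cm/px preserving the 14.5 × 21.8 cm physical
field, so a 5 mm bin is exactly 25 rows (the original camera's exact pixel
pitch is unpublished, so this geometry is a convention that preserves
physical scales, and it is configurable). Response-curve defaults follow the
qualitative shapes of the reported relationships: live/dead ratio
$50 e^{-1.3 p} + 0.5$ (control ratios centred near 50, decaying towards zero
at high pressure), penetration $16 - 2p$ cm, rugosity $3 e^{-1.2p} + 0.5$,
interstitial fraction $0.25 e^{-0.8p} + 0.05$, thallus perimeter
$600 - 80p$ px and solidity $0.60 + 0.07p$. Noise is per image: additive
Gaussian truncated to admissible ranges for all metrics except the live/dead
ratio, which takes multiplicative lognormal noise (log-SD 0.35) because a
ratio is strictly positive and right-skewed — the lognormal keeps control
stations spread roughly ±40% while leaving the fitted decay rate unbiased.

Scenes are constructed truth-first: class labels are allocated *exactly* per
5 mm bin (largest-remainder rounding of the target fractions, positions
shuffled within the bin), so stored per-bin truths are attained by
construction; pixel colors are then drawn from per-class independent
Gaussians clipped to 0--255, and at zero color noise classification recovers
the truth mask for 100% of below-interface pixels. Campaign compositions are
constant with depth (the live/dead split set from the target ratio);
depth-banded compositions are exercised directly through
`generate_spi_image()`. The interface is a reflected random walk whose step
magnitude is scaled so the expected rugosity matches the target; integer
rounding of the trace makes achieved metrics differ slightly from targets,
and all stored truths are the *achieved* values, recomputed from the realized
trace and mask with the same closed formulas the estimators use — so
truth self-consistency is exact while target recovery is statistical.

AIS effort is laid down as within-cell passes whose total in-window length is
exactly `pressure × 2500 / 1.5` m, spread round-robin over five seasons, plus
out-of-window decoy transits; pings are emitted at a fixed interval *and* at
every polyline vertex, so ping chords never cut corners and the recovery
pipeline reproduces the prescribed per-cell pressures to floating-point
accuracy. An out-of-window transit ping separates consecutive passes of the
same vessel so the maximal-run rule cannot bridge them. Thalli are six-spiked
stars: for that family solidity is analytically $(r/R)/\cos(\pi/6)$, so the
inner/outer radius ratio is solved from the target solidity and the size from
the target perimeter, giving exact continuous truths for every rendered
thallus.

What the generator does *not* emulate: photorealistic maerl texture, optical
effects of the SPI prism, lighting gradients, species mixtures, tides or
currents in vessel motion, and spatial autocorrelation between neighbouring
stations. Passing tests therefore demonstrate that the estimators recover
known structure of this idealized kind — color-threshold separability,
exact interface traces, independent station noise — not that the thresholds
themselves are right for any particular camera or bed.

## Problem sizes and determinism

The test-suite and acceptance runs use reduced problem sizes chosen to keep
the full suite in the low minutes while leaving every statistical check
well-powered: rendered pipeline campaigns of 6 stations × 5 images at
145 × 218 px (0.1 cm/px — the same 14.5 × 21.8 cm physical field), 100-seed
Monte-Carlo replication for parameter recovery at the full 30 × 15 design
(metric level, images not rendered), 1000 (suite) or 500 (script) null
simulations for test size, and exhaustive permutation wherever the
arrangement count allows. Every random step is seeded; campaigns derive
per-stage seeds from one root seed, so stages are independently reproducible
and identical configurations give byte-identical outputs (manifests differ
only in their timestamp).

## Known limitations

* The interface trace is an input; no automatic interface detection is
  attempted.
* Classification is purely per-pixel; no spatial regularization, lighting
  correction or species-level discrimination.
* Whether the live/dead quantity is a raw area ratio or a percentage of
  cover is ambiguous in the source description; the package computes the raw
  ratio.
* PERMDISP is slightly liberal for groups smaller than ~10 (above).
* The pressure raster ignores geodetic projection — inputs must already be
  in projected metres — and gear behaviour beyond the speed window.
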