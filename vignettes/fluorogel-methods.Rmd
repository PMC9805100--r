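---
title: "Methods: automated densitometry and classification of fluorescent SDS-PAGE gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated densitometry and classification of fluorescent SDS-PAGE gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorogel)
```

## The analysis problem

A fluorescence-labelled SDS-PAGE experiment yields a two-channel scan: the
labelled protein in a sample channel and a fluorescent molecular-weight
ladder in a marker channel. The scientific object of interest is not the raw
image but the *mass-calibrated intensity profile* of each lane — intensity
as a function of molecular mass — because only on a common mass axis can
patterns be compared quantitatively across lanes, gels and laboratories.
`fluorogel` turns raw scans into such profiles, quantifies the absolute
degree of labelling, and classifies unknown lanes against a digital
reference library of modification patterns.

## Geometry: edges, rotation, lanes

**Edge detection.** The gel boundary columns are the strongest rising and
falling steps of the column-sum projection of the channel-summed image; the
stacking/resolving border is the strongest rising step of the row-sum
projection in the upper third (the resolving gel scatters more light than
the stacking gel, so the border is a horizontal intensity step); the
cassette bottom is the lowest row whose summed intensity stands clearly
above the off-gel baseline. Working on 1-D projections rather than 2-D edge
maps is deliberate: it is parameter-light and invariant under uniform
intensity scaling. A detection is rejected ("no gel detected") when the
strongest projection step does not exceed `significance` (default 5) times
the median gradient magnitude, so featureless images fail loudly rather
than returning nonsense.

**Rotation.** Scanners and gel placement introduce a small global rotation.
The correction angle is found by exhaustive grid search (default ±5° in 0.1°
steps) maximising the variance of the column-sum projection of the
band-bearing region after rotation by the candidate angle: vertical lanes
concentrate bands and inter-lane gaps into the sharpest columnwise
structure. Three numerical details matter and are easy to get wrong:

* the projection is computed by per-row horizontal shear with linear
  interpolation rather than by resampling the full image — the vertical
  component of a small rotation cancels inside a column sum, and no fill
  values ever enter the score;
* every candidate angle is scored on the same central column window (the
  region is inset by the maximal shear of the search range), so the gel's
  own boundary edges and partially covered columns cannot bias the
  comparison;
* a deterministic per-row sub-pixel phase dither (golden-ratio sequence)
  makes the interpolation kernels statistically identical across candidate
  angles. Without it, angle 0 — where samples fall exactly on the pixel
  grid and escape interpolation blur — receives a spurious sharpness bonus,
  and small true rotations are systematically pulled to zero.

Ties break toward the smallest |angle|, negative before positive, so a
featureless region returns 0. On simulated gels with band signal-to-noise
ratio of about 10 or better the applied angle is recovered within 0.3°
(one test asserts exactly this across ±4°); rectification uses inverse-map
bilinear rotation about the image centre, filling from the border-pixel
median so the dark margin, not the gel interior, supplies out-of-frame
values.

**Lanes.** Lane boundaries are a fixed equal-width partition of the gel
columns into the declared number of lanes, remainder pixels distributed one
per lane from the left. No per-lane refinement is attempted — lane-finding
heuristics fail in exactly the low-signal lanes this assay cares about,
whereas the loading comb geometry genuinely is equidistant.

## Profiles, baseline, bands

Migration distance is measured in pixels from the stacking/resolving border
(distance 0), increasing downward. A lane profile sums pixel intensity
across the lane width at each distance, so the profiles of all lanes
partition the gel-region intensity exactly — an invariant the tests check
to the last unit.

**Baseline.** Gels carry diffuse background: membrane autofluorescence,
lane smear, and a slow vertical gradient. The baseline estimator is a
two-pass design chosen after the obvious candidates failed quantitatively:

1. a running median (window 51 px by default) smoothed by a local linear
   smoother of the same window gives a first estimate — unbiased under
   zero-mean noise and exact on linear ramps (a rolling-minimum "envelope"
   baseline, by contrast, sits one noise amplitude below the background
   and systematically inflates lane totals on noisy gels);
2. samples more than 3 robust standard deviations above that baseline
   (floored at 1 % of the largest excursion, so that near-noiseless
   profiles do not mask their own baseline wiggle) are flagged as band
   territory, dilated by a quarter window to cover band tails, and the
   baseline is re-estimated by linear interpolation across the flagged
   spans — removing the small upward pull that band tails exert on a plain
   running median.

The smoother is Savitzky–Golay of degree 1: identical to a moving average
in the interior but fitted on shrinking windows at the profile ends, which
avoids the edge artefacts that padding schemes introduce next to the
stacking/resolving step. The subtracted profile is clipped at zero for
band detection and plotting, but the profile also carries
`residual_total`, the unclipped sum of profile minus baseline: clipping
turns zero-mean noise into a positive residue that would bias absolute
quantification by several percent, whereas the unclipped total lets that
noise cancel.

**Band detection.** Bands are local maxima with topographic prominence —
height above the highest saddle separating the peak from any higher peak —
of at least `min_prominence` (default 0.05) times the profile maximum.
Prominence is the right statistic here because it is insensitive to the
absolute exposure and to broad pedestals; the relative threshold makes
detection invariant under exposure scaling (an absolute-threshold override
exists, useful for lanes that contain no real signal at all, where any
relative threshold promotes noise). Equal-height plateaus take their
leftmost sample as apex; band area integrates between the two local minima
flanking the apex. Both the peak set and the prominences are verified in
the tests against an exhaustive brute-force oracle.

## Mass calibration

Ladder masses are paired to detected marker bands in migration order
(least-migrated band, largest mass). Surplus detections are pruned to the
subset with maximal total prominence — since the bands are already in
distance order, this is simply the most prominent ones, a fact the tests
confirm against full subset enumeration. Missing bands are an error, not a
guess: extrapolating a ladder from too few anchors silently corrupts every
downstream mass.

The calibration itself is the piecewise-linear interpolant of
(distance, log10 mass) through the anchors, continued beyond the end
anchors with the adjacent segment's slope. Interpolation — not regression —
is intentional: marker masses are certified values and the mapping should
pass through them exactly. Log-mass versus linear distance is the standard
electrophoresis relation; a sigmoidal or Ferguson-type model is out of
scope. Masses assigned outside the anchor span are flagged `extrapolated`
in all exports, because extrapolated assignments are markedly less
reliable.

**Common mass axis.** Profiles are rebinned onto a shared log-spaced grid
(default 500 cells, 260 down to 10 kDa, spanning typical prestained
ladders). Each unit pixel interval maps to its mass interval under the
calibration and deposits its intensity into grid cells proportionally to
overlap in log10-mass coordinates. This conservative rebinning is exactly
linear in the profile and conserves total intensity wherever the grid
covers the profile's mass span; intensity calibrated outside the grid is
dropped by design, so conservation checks (and users comparing totals)
should choose a covering grid.

**Bleed correction.** A strong sample fluorophore can leak into the marker
channel through its long-wavelength emission shoulder. Before marker
detection the pipeline (optionally, default on) estimates the leak
coefficient k by least squares of the marker channel's
background-corrected signal on the sample channel's over all non-marker
lanes — where the marker channel should contain nothing — clips k to
[0, 1], and subtracts k times the sample signal everywhere.

## Absolute quantification

A fluorophore dilution series gives an OLS standard curve
intensity = slope·moles + intercept. The intercept is kept free because
real scanners have blank offsets; a true zero-offset series still recovers
intercept 0 exactly. A lane's fluorophore amount is the inverted curve at
the lane's unclipped residual total; dividing by the moles of protein
loaded gives the degree of labelling in percent — which may legitimately
exceed 100 % when molecules carry several labels — and dividing that by
the lysine count per molecule gives the fraction of lysines labelled.
Negative inferred amounts (blank lanes) clip to zero with a warning rather
than erroring, since empty lanes are routine. The lysine count is a user
parameter: it is protein-specific and cannot be inferred from the gel.

## Reference libraries and classification

A reference library stores labelled mass profiles on one shared grid and
serializes to a JSON manifest plus a CSV matrix — human-inspectable,
diff-able, and written at full double precision so the round trip is
bit-exact. Classification computes the squared Pearson correlation R²
between a query profile and every entry, full mass range by default, and
ranks the entries. Correlation is computed on raw rebinned intensities
with no smoothing or normalisation: Pearson's affine invariance already
absorbs exposure scaling and offsets, which is precisely the property that
makes profiles comparable across independently run gels. Ties go to the
first entry in library order and are flagged. Zero-variance profiles are
an error, not a zero: a constant profile has no pattern to correlate.

## The simulator: what it emulates, what it does not

`simulate_gel()` renders the study conditions the analysis targets: a
520×460 px scan with a 390-px-wide gel, stacking/resolving background step
(stacking at 35 % of the resolving level — the step is what makes the
border detectable), a 10 % vertical background ramp, log-linear migration
with a = 606 px and b = 240 px per decade (placing 250–25 kDa across
20–270 px of a 410-px resolving region), Gaussian bands (σ = 3 px) spread
over 70 % of the lane width (real wells are narrower than the lane pitch,
leaving the dark inter-lane gaps that rotation estimation keys on), a 5 %
continuous lane smear, marker amounts of 0.5 nmol per rung, sample bands
of 0.4–1 nmol at 10⁴ intensity units per nmol, emission-shoulder bleed
k = 0.1 into the marker channel, global rotation, exposure scaling, and
additive Gaussian noise (optionally Poisson). Ground truth records every
band's position, mass and intensity, the geometry, the rotation and the
per-lane fluorophore amounts — including the smear, which is labelled
material.

Class-pattern simulation renders near-blank "native", UV-like, heat-like
and deglycosylation-like band sets, with per-band multiplicative jitter,
per-replicate exposure scaling in [0.5, 2], and additive noise, emulating
the same samples re-run on independent gels.

What the simulator does **not** emulate — and hence what passing tests do
not demonstrate about real data: lane curvature ("smiling"), keystone or
perspective distortion, saturation and blooming, spatially correlated
background texture, Ferguson-plot nonlinearity of migration, and
protein-dependent staining efficiency. The default migration law is
exactly the log-linear idealisation the calibration assumes; a mild
quadratic `curvature` option exists to probe robustness but is off by
default.

Problem sizes in the tests and the acceptance script are one gel per
scenario, nine rotation angles, two query gels for classification, and
1000 random evaluation points for the calibration law — sizes at which
every quantity checked is already at its asymptotic accuracy.

## Design choices on genuinely open points

* **Rotation criterion.** The optimisation target for rotation is not
  dictated by gel physics; variance of the column-sum projection is this
  package's choice, implemented via shear projection with the safeguards
  described above.
* **Background handling** is likewise an open design point; the two-pass
  median/interpolation baseline and the unclipped quantification total are
  this package's answers, chosen for unbiasedness under noise and exactness
  on ramps.
* **Interpolation space.** Log10-mass versus linear distance, with a
  log-spaced common grid of 500 cells from 260 to 10 kDa; both density and
  range are configurable.
* **Full-range correlation.** R² is computed over the whole shared grid by
  default; a mass-window restriction is available for excluding
  extrapolated grid regions.
* **Coordinates.** Rows and columns are 1-based (R convention); migration
  distance starts at 0 at the stacking/resolving border and increases in
  the direction of migration.

## Known limitations

Geometry correction is a single global rotation: curved or keystoned lanes
are out of scope. Lane boundaries trust the declared lane count. Absolute
quantification assumes the fluorophore's response on the gel matches the
dilution series (no environment or quantum-yield correction) and reports
per-lane, not per-band, stoichiometry. Classification is 1-D nearest-
neighbour by R²; it has no rejection class, so a query unlike every
reference still gets a best match — inspect the R² values, not only the
labels. Very close bands (closer than about half the baseline window)
partially absorb each other's baseline and may have their prominences
underestimated.
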