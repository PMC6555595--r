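---
title: "Quantifying cortical Par-complex polarity: methods and design notes"
author: "parcortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical Par-complex polarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcortex)
```

## Scope

`parcortex` quantifies cortical polarity of the Par complex (Par3, Par6,
atypical protein kinase C) as reconstructed in cultured cells: how one-sided
the cortical fluorescence is (the asymmetric index), how strongly curved the
membrane is where Par-islands sit, whether the island meshwork has a
recurring unit-segment length, how large Par aggregates are, and whether the
centrosome falls inside the angular sector spanned by the cortical crescent.
Image segmentation and tracing are deliberately out of scope: contours,
island spans, segment endpoints and ROI polygons are inputs, because in
practice they are traced by hand in Fiji or similar, and the statistics
should not depend on an automatic tracer of unknown behaviour. All analysis
is carried out in micrometres; pixel sizes (0.108 µm for confocal work,
0.053 µm for super-resolution reconstructions) are applied on ingest.

## The asymmetric index

A closed equatorial intensity profile is sampled at n (even) equally spaced
arc positions. For every contiguous window of n/2 samples, the absolute
difference between the intensity summed inside the window and in the
complementary half is divided by the total intensity; the asymmetric index
(ASI) is the maximum over all n windows:

$$\mathrm{ASI} = \max_i \frac{\left| \sum_{j \in W_i} I_j -
\sum_{j \notin W_i} I_j \right|}{\sum_j I_j},
\qquad |W_i| = n/2 .$$

A uniform profile gives 0, a profile fully concentrated in one contiguous
half gives 1. The statistic is invariant under cyclic rotation, orientation
reversal and positive rescaling of the profile, and adding a constant
baseline strictly decreases any positive ASI (the numerator is unchanged,
the denominator grows) — so background subtraction matters when comparing
cohorts. The implementation evaluates all windows in O(n) from a cumulative
sum; the test suite pins it against an exhaustive O(n²) oracle to 1e-12.

```{r asi}
asi(c(rep(5, 100), rep(1, 100)))
```

A cell is *polarized* when ASI strictly exceeds 0.35. This cutoff is the
upper end of the ASI range produced by membrane-bound GFP, a marker that
cannot polarize, so larger values cannot be explained by fluctuation of a
uniform cortical signal. The boundary value 0.35 itself is classified
non-polarized.

Design points:

* Profiles of odd length are resampled to the next even count by linear
  interpolation along arc length (the half-window definition needs a
  divisible perimeter); total arc length is preserved.
* When a profile is extracted from an image (`extract_perimeter_profile()`),
  each sample is the *mean* intensity across a 0.5 µm band perpendicular to
  the contour. Mean rather than sum keeps profile values independent of the
  band sampling density; ASI is invariant to this choice either way.
* Ties in the maximizing window go to the smallest start index.

## Membrane curvature from three points

The local curvature radius of a membrane region is the radius of the circle
through three of its points — the two region endpoints and the point at half
its arc length: $R = abc / (4K)$ with $a,b,c$ the triangle side lengths and
$K$ its area. Triangles with area below 1e-9 µm² are treated as straight
membrane (infinite radius); such regions are excluded from summaries rather
than recorded as huge radii.

Regions are classified relative to Par-islands along the closed equatorial
contour:

* **island** — a span co-localizing with Par signal, longer than 1 µm;
* **neighboring** — membrane within 5 µm (arc distance, shorter way around)
  of an island edge; classified but *not* measured, since island proximity
  perturbs curvature;
* **non-neighboring** — the remaining stretches, split into consecutive
  compartments of at most 5 µm starting at the exclusion-zone boundary;
* **non_island_cell** — in cells without islands, the whole contour is split
  into compartments of at most 5 µm (5–6 per cell for typical S2-cell
  perimeters of 25–30 µm).

The splitting rule for long stretches (consecutive ≤ 5 µm compartments from
the exclusion boundary, remainder last) is a declared convention: any
partition into sub-5 µm compartments would do, and the package makes the
choice deterministic. Group distributions are compared by two-sample
Kolmogorov–Smirnov tests on the radii, with per-group medians reported,
because radius distributions are heavy-tailed and medians are the robust
location summary.

## Meshwork periodicity

Traced contour lengths from super-resolution images are summarized in three
steps.

**Kernel density.** `length_density()` computes a Gaussian KDE on a uniform
512-point grid over [0, max + 3·bandwidth]. The default bandwidth is the
Sheather–Jones plug-in (`stats::bw.SJ`). Silverman's rule-of-thumb is also
available but is a poor default here: it scales with the overall sample
standard deviation, which for a comb-like sample is dominated by the spread
of the comb teeth rather than their width, and at the study conditions
(component sd about 6% of the spacing) it oversmooths the comb into a
unimodal curve. Bandwidth remains a user-visible parameter because peak
resolvability depends on it.

**Gaussian comb fit.** `fit_k_gaussians()` fits
$y(x) = \sum_{j=1}^{k} A_j e^{-(x-\mu_j)^2 / 2\sigma_j^2}$ (default k = 7)
to the density curve by bounded Levenberg–Marquardt least squares
($A_j \ge 0$, $\sigma_j > 0$, $\mu_j$ inside the grid). Initial means are
placed at the k tallest local maxima of the density (padded with evenly
spaced positions when fewer exist), $\sigma_j$ at the KDE bandwidth and
$A_j$ at the density height; up to 10 seeded random restarts are tried on
non-convergence. Evenly spaced initialization across the whole grid was
considered and rejected: it frequently converges to a non-comb local
optimum when the first and last teeth carry little mass. Non-convergence is
an error carrying the best residual, never silently absorbed: if k exceeds
the resolvable modes the user should see it. The *peak interval* — the mean
and sd of the k−1 consecutive differences of the sorted fitted means — is
the unit-segment length estimate. (For a per-cell averaging reading of the
summary, apply the fit per cell and average the intervals; both routes are
available since the fit exposes its component means.)

```{r comb}
lengths <- make_comb_lengths(754, 0.38, 0.06 * 0.38, k = 7, seed = 1)
dens <- length_density(lengths$lengths_um)
fit <- fit_k_gaussians(dens, k = 7, seed = 1)
round(c(interval = fit$peak_interval_mean_um, sd = fit$peak_interval_sd_um), 4)
```

**Spectral route.** `spectral_periodicity()` takes the second derivative of
the density curve by central differences, zero-pads to the next power of
two, and takes the squared-magnitude FFT. The major frequency is the argmax
over strictly positive frequencies (zero bin excluded, ties to the lowest
frequency); its reciprocal is the implied repeat interval. Differentiating
twice multiplies spectral power by $(2\pi f)^4$, which has two consequences
worth knowing:

* On a *sharply* resolved comb (e.g. an SJ-bandwidth density of a
  low-variance sample) a harmonic of the comb frequency can carry the most
  power. The two routes (comb fit vs spectrum) agree at moderate smoothing
  — about 0.09 µm bandwidth for 0.3–0.5 µm combs — and the package's
  consistency test evaluates the agreement there.
* A smooth aperiodic density still has a spectral maximum somewhere. The
  `periodic` flag therefore requires the major peak to stand at least twice
  above the median positive-frequency power *and* to have a quality factor
  (frequency divided by half-power width) of at least 2 — i.e. the implied
  repeat must fit about twice into the density's support. A single-Gaussian
  density fails this and is flagged aperiodic.

**Segment statistics.** Straight segment lengths (endpoint distances) are
summarized by mean, sd and a single-Gaussian fit to their histogram. Segment
width is the full width at half maximum of a Gaussian-plus-baseline fit to a
cross-section profile, $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$; profiles
without an interior peak are rejected rather than fitted.

## Aggregate sizes, fan geometry, cohort statistics

ROI polygon areas use the shoelace formula; self-intersecting polygons are
rejected, and polygons touching the optical-section limit should be excluded
upstream. Group size distributions are compared with two-sample KS tests.

The fan test works in image coordinates (y down) with clockwise-positive
angles: θ1 is the clockwise angle from the first crescent edge to the
second, seen from the cell centre; θ2 the clockwise angle from the first
edge to the centrosome direction. The centrosome is inside the fan when
0 ≤ θ2 ≤ θ1, boundaries inclusive, so measurement noise cannot exclude a
centrosome sitting exactly on an edge. Which edge anchors the measurement is
a data convention: input files must list the edge from which angles are
measured first.

Polarized-cell fractions across conditions are compared against a reference
by Fisher's exact test on 2×2 counts with Bonferroni correction (multiplier
= number of comparisons, capped at 1). Expression levels per cell divide
blot intensities by transfection efficiencies before forming fold ratios.

## The synthetic-data generator

Every pipeline input can be generated with an explicit seed and a
ground-truth record: crescent profiles (known exact ASI), circular arc
points (known radius), Gaussian-comb length samples (known spacing),
meshwork lattice rasters (known edge lengths and line mask), Gaussian
cross-sections (known FWHM), and centrosome–crescent cohorts (known
within-fan fraction, exact by construction). Defaults mirror the observed
scales of the system: cell radii of 4–5 µm, comb spacing 0.38 µm with
component sd 6% of the spacing, 754 contour lengths, 194 segments, cohorts
of 40 fan configurations with 80% inside, pixel sizes 0.108 and 0.053 µm.
Noise is additive Gaussian, truncated at zero because fluorescence is
non-negative; comb samples re-draw negative values instead of clipping so
components stay Gaussian. Noise and intensity levels are free parameters —
no calibration for any modality is available — so they are chosen at
moderate, realistic contrast (e.g. 5% amplitude noise on cross-sections).

What the generator does *not* emulate: point-spread-function blur beyond a
drawn line width, shot-noise statistics, out-of-focus background, tracing
error of a human annotator, and spatial correlation of noise. Passing tests
therefore demonstrate correctness of the estimators on data of known
structure, not robustness to every artefact of real microscopy.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest problem
sizes — 200–1000 random profiles or circles per property, 50 seeded
replicates per comb condition, 100 seeds for the noise studies — chosen so
the whole suite completes in well under a minute per module while keeping
binomial success criteria (e.g. "at least 90% of fits within 10%")
meaningful. Collinearity uses a 1e-9 µm² area tolerance; KDE grids use 512
points; spectral padding goes to the next power of two; optimizer
convergence follows `minpack.lm` termination codes 1–3 with up to 10
restarts. All randomness is seed-controlled, and generators are
byte-reproducible for a fixed seed.

## Known limitations

* The ASI presumes a closed, roughly convex equatorial contour; strongly
  re-entrant membranes make the arc-length parameterization of the band
  ambiguous.
* Curvature from three points is exact on circular arcs but biased on
  regions whose curvature varies along the arc; the region length caps
  (≤ 5 µm) limit, not eliminate, this.
* The comb fit needs the density to actually resolve the modes: at
  bandwidths above roughly a third of the spacing, neighbouring teeth merge
  and k = 7 becomes unidentifiable (surfaced as a convergence error).
* The spectral flag is a heuristic; densities with exactly two repeats sit
  near its quality-factor boundary.
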