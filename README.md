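# parcortex

Quantification of reconstructed cortical Par-complex polarity in cultured
cells.

When Par3 is overexpressed in otherwise apolar cells (such as *Drosophila*
S2 cells), the Par complex (Par3, Par6, atypical protein kinase C)
aggregates at the cortex into dots and micrometre-scale "islands" that can
cluster to one side of the cell. `parcortex` implements the quantitative
side of characterizing that reconstructed polarity, for cell biologists
measuring traced microscopy data and for anyone who wants the statistics
reproducible and testable:

* **Asymmetric index (ASI)** — for a closed equatorial intensity profile
  with an even number n of equally spaced samples,

  ASI = max over all n contiguous half-perimeter windows W of
  |Σ<sub>W</sub> I − Σ<sub>W̄</sub> I| / Σ I,

  computed in O(n) and checked against an exhaustive oracle; cells with
  ASI > 0.35 are classified polarized (the cutoff is the upper end of the
  range a non-polarizable membrane marker produces).
* **Membrane curvature** — radius of the circle through a region's two
  endpoints and arc midpoint, R = abc/4K; membrane regions are classified
  as Par-island (> 1 µm), neighboring (within 5 µm of an island edge,
  excluded from measurement) or non-neighboring compartments (≤ 5 µm),
  with per-group medians and Kolmogorov–Smirnov comparisons.
* **Meshwork periodicity** — kernel density of traced contour lengths, a
  bounded least-squares fit of a 7-Gaussian comb whose consecutive
  mean-spacing estimates the unit-segment length, and an independent
  spectral route (power spectrum of the density's second derivative).
* **Segment statistics** — straight segment lengths with a Gaussian
  summary fit, and segment width as the FWHM (= 2√(2 ln 2) σ) of a
  Gaussian-plus-baseline fit to a cross-section profile.
* **Morphometrics and geometry** — shoelace ROI areas of Par aggregates,
  centrosome–crescent fan geometry (is the centrosome inside the angular
  sector θ1 spanned by the crescent?), per-cell expression ratios, and
  Fisher's exact tests of polarized fractions with Bonferroni correction.
* **Synthetic data** — seeded generators for every input type with exact
  ground truth, so the whole pipeline is verifiable without raw images.

## Worked example

```r
library(parcortex)

# a 400-sample equatorial profile with a 25% crescent at 5x contrast, noise
p <- make_perimeter_profile(400, 0.25, 5, 1, 0.3, seed = 42)
asi(p$profile)
#> ASI = 0.5096 (polarized at threshold 0.35), half-window start index 200

# 754 contour lengths from a 0.38 um comb; KDE + 7-Gaussian fit
cl  <- make_comb_lengths(754, 0.38, 0.06 * 0.38, k = 7, seed = 42)
fit <- fit_k_gaussians(length_density(cl$lengths_um), k = 7, seed = 42)
round(fit$components$mean_um, 3)
#> [1] 0.375 0.759 1.141 1.519 1.902 2.277 2.660
c(fit$peak_interval_mean_um, fit$peak_interval_sd_um)
#> 0.381 0.004      # unit-segment length estimate (um)

# independent spectral route on a moderately smoothed density
sp <- spectral_periodicity(length_density(cl$lengths_um, bandwidth = 0.09))
sp$major_frequency_um_inv; sp$implied_interval_um
#> 2.67             # per um
#> 0.375            # um, consistent with the comb fit
```

The ASI of 0.51 says half the perimeter carries substantially more signal
than the other half — a polarized cell. The fitted comb means sit 0.381 ±
0.004 µm apart, recovering the generating 0.38 µm spacing; the spectral
major frequency of 2.67 µm⁻¹ implies 0.375 µm, the same repeat length by an
independent route.

Curvature of a 30 µm contour (radius 4.77 µm) with one 3 µm island:

```r
tr <- membrane_trace(circle_coords, island_spans = cbind(4, 7))
measure_trace_curvature(tr)
#>      region_class start_um end_um radius_um
#> 1          island        4      7     4.775
#> 2 non_neighboring       12     17     4.775
#> ...
```

Every region on a perfect circle returns the generating radius; the 5 µm
exclusion zones flanking the island are classified `neighboring` and not
measured.

## Package layout

```
R/                      ASI, curvature, meshwork, geometry, synthetic, I/O
tests/testthat/         unit + property tests, oracle helpers, acceptance
scripts/acceptance.R    headline-quantity recomputation (JSON out)
vignettes/              methods and design notes
```

See `vignettes/par-polarity-quantification.Rmd` for the models,
assumptions, parameter defaults and known limitations.
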