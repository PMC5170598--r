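---
title: "Mapping irrigated area from NDVI time series: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping irrigated area from NDVI time series: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irrimap)
```

## The problem and the model

Irrigated and rainfed fields of the same crop trace similar seasonal NDVI
curves, but irrigation relieves water stress during the growing season, so
the irrigated curve attains a visibly higher seasonal peak. `irrimap`
exploits that single, robust contrast in two stages: first pixels are
grouped into crop classes by the *shape* of their annual NDVI profile,
then within each class a peak-NDVI threshold derived from the class's own
condition statistics separates irrigated from rainfed members. Because the
threshold is relative to the class, no calibration against census area is
needed.

All layers live on one north-up, square-pixel grid (`grid_spec`), nominal
250 m, where one pixel represents 6.25 ha. The time axis is the *water
year*: June 1 of year Y through May 31 of year Y+1, giving 23 sixteen-day
composites. Composites are stacked (`build_ndvic`) strictly by start date
and used without temporal smoothing; smoothing buys little accuracy for
crop classification and has caused inconsistencies in earlier efforts.

## Stage 1: crop typing

**Masking.** Only pixels whose land-cover code is agricultural and whose
slope is at most 20% enter the analysis (`agricultural_mask`). The 20%
figure is the operative masking threshold, kept configurable; the mask is
season-agnostic, and the zone map (`partition_by_zone`) splits the masked
extent so every downstream statistic is calibrated per agroecological
zone.

**Phenology.** Emergence and senescence are read from the cumulative
departure of the profile from its own mean: the running sum
$C_t=\sum_{s\le t}(x_s-\bar x)$ is minimal when the curve turns from
below-mean to above-mean (emergence). The rule as stated fixes only the
minimum; this package defines senescence as the *later maximum* of $C_t$
— the above-mean to below-mean crossing — which is the natural dual and
recovers generated season ends within one composite on noise-free
single-season profiles. Ties take the earliest composite, constant
profiles are rejected as season-free, and interior `NA` gaps are linearly
interpolated (gaps longer than 3 composites disqualify a training pixel).

**Seasonal windows.** The year is cut into a first (Kharif, composites
0–9), second (Rabi, 10–18) and intermediate (Zaid, 19–22) season window
plus the complete year, proportionally rescaled for other stack lengths
and configurable per zone, since sowing calendars shift with region.

**Height and the lookup table.** The seasonal peak NDVI is rescaled so
0.1–0.8 maps linearly onto 1–100 ("height"), clamped at both ends; the
croppable NDVI range rarely leaves that interval and rainfed NDVI does not
saturate. Crop labels come from a per-zone lookup table — season, duration
interval, height interval, scanned in explicit priority order so
overlapping entries resolve deterministically. The packaged table
(`default_crop_lookup`) is *synthetic*: it is generated to be consistent
with the scene generator and is labelled non-authoritative; real
applications must supply a literature-derived table because the original
height values are not published.

**Training and signatures.** Training candidates sit on a deterministic
lattice every 4 km (every 16th pixel at 250 m), a spacing that keeps
samples spatially spread while yielding enough labelled profiles per zone.
Each crop's end-member signature is the composite-wise mean of its member
profiles; crops with fewer than 3 members are dropped and reported rather
than fitted from noise.

**Classification.** The Spectral Correlation Mapper score is the Pearson
correlation between the pixel profile and the signature: centering on both
means distinguishes negative from positive correlation, which the
uncentered Spectral Angle Mapper cannot. The score range is the full
$[-1,1]$, but assignment never uses a non-positive best score, and a floor
(default 0.5, configurable) rejects weak matches — the original method
states no floor, so the default errs on the side of leaving doubtful
pixels unclassified rather than pushing them into the irrigation stage.
Ties go to the lowest class id. The vectorised classifier is tested for
exact agreement with a brute-force double-loop oracle.

## Stage 2: the irrigation decision tree

For a crop class, let $NDVI_{imclass,i}$ be the peak-NDVI ceiling of the
class's $i$-th *seasonal pool*, $i = 1..n$. Then

$$NDVI_{mclass}=\tfrac1n\sum_i NDVI_{imclass,i},\quad
  NDVI_{mp}=\min_i NDVI_{imclass,i},$$
$$MVCI=\frac{NDVI_{mp}-NDVI_{mclass}}{NDVI_{mclass}},\qquad
  NDVI_{irclass}=MVCI\cdot NDVI_{mp}+NDVI_{mp}.$$

$MVCI\le 0$ always, so $NDVI_{irclass}\le NDVI_{mp}\le NDVI_{mclass}$; a
single pool (or all-equal pools) collapses the threshold to $NDVI_{mp}$.
MVCI is applied as a fraction: multiplying by 100 yields the percentage
form used for reporting, but a percentage inside the threshold equation
would drive it far outside the NDVI range, so the fractional reading is
the only self-consistent one.

A pixel of the class with seasonal peak $v$ (the peak of its best pool,
i.e. its water-year maximum) is labelled irrigated when

$$v\ \ge\ \max(NDVI_{irclass},\,0.2)
  \quad\text{and}\quad v-NDVI_{mp}\ \ge\ 0.15 .$$

The 0.2 floor keeps sparse or bare classes out; the 0.15 clause demands a
genuine peak gap above the class's stressed ceiling. Both constants are
configuration keys with these defaults. The separation clause is evaluated
per pixel (the pixel's own class value against the class $NDVI_{mp}$): a
class-level reading would make the rule all-or-nothing per class, which
contradicts its use as a per-pixel separator. Multi-season pixels
irrigated in any pool count as irrigated — the product is binary and a
partially irrigated pixel counts fully.

**What a seasonal pool is.** The growing-stage pools of a crop class are
described, in the source method, as *spectral subclasses of the individual
crop*. Two readings were open: temporal windows (the season windows above)
or condition subclasses. Temporal windows make the statistics degenerate —
for a single-season crop the within-season ceiling is the class maximum,
so $v-NDVI_{mp}\ge 0.15$ can never hold, and including off-season windows
drags $NDVI_{mp}$ to the bare-soil level so every green pixel passes.
Condition subclasses make the algebra do exactly what the worked threshold
example implies: with pools at ceilings 0.6/0.8/0.7 the stressed ceiling
0.6 is the rainfed maximum and the rule separates a 0.78-peak pixel from a
0.70 one. This package therefore forms pools *within* a class by ranking
member pixels on seasonal peak NDVI and cutting the ranking into `n`
equal-count groups (default `n = 3`, deterministic, stable under heavily
tied peaks). The lowest pool's ceiling then estimates the rainfed maximum
of the class. A class that is entirely irrigated (or entirely rainfed) has
no internal contrast and yields no (or no spurious) irrigated labels; the
method intrinsically needs both conditions present in a class, which holds
whenever a zone mixes irrigated and rainfed fields of a crop.

## The synthetic scene generator

`generate_scene` emulates what the classifier assumes about real data:
per-pixel double-logistic seasonal NDVI curves with crop-specific sowing
and duration, an irrigated peak exactly `irrigated_boost` above the
rainfed peak of the same crop, additive i.i.d. Gaussian composite noise,
matching land-cover/slope/zone layers, and RED/NIR stacks solved so that
$NDVI=(NIR-RED)/(NIR+RED)$ holds identically. Defaults are the study
conditions: 64×64 pixels at 250 m, 23 composites, two crops (a Kharif and
a Rabi cereal, rainfed peak 0.6), boost 0.2, noise sd 0.02, half the
cropland irrigated, 20% non-agricultural pixels, 5% steep terrain.
`scenario_drought` scales rainfed peaks by a deficit while irrigated peaks
stay put (groundwater-buffered), and can leave a fraction of irrigated
pixels unsown; random draws are taken in a fixed order so base and
scenario scenes share pixel identities, and a zero-deficit scenario is
bit-identical to its base.

What the generator does *not* emulate — mixed pixels at field boundaries,
cloud-gap structure, spatially correlated weather anomalies, crop rotation
within a pixel, lookup-table error — bounds what passing tests show:
recovery on these scenes demonstrates the algorithm's internal
consistency, not survey-grade accuracy on real archives.

## Numerical conventions and edge cases

* Pixel `(r, c)` footprints are half-open, north-up; row/column indices
  are 1-based in the R API (matrix convention), while composite indices in
  descriptors are 0-based offsets into the water year, matching composite
  numbering.
* Resampling (`align_to_grid`) uses area-weighted majority (ties to the
  lowest code) or area-weighted mean; CRS mismatches are refused, never
  silently reprojected. Polygon membership is pixel-center-in-polygon.
* TIFF samples only represent $[0,1]$, so `write_raster` rescales values
  into that interval and reserves stored 0 for nodata, declaring the
  mapping in a JSON sidecar; integer layers round-trip exactly, float
  layers to better than $10^{-6}$ for NDVI-range data. The integer-scaled
  archive convention (scale factor $10^{-4}$) is honoured only when the
  sidecar declares it.
* Height scaling clamps its *output* to $[1,100]$: at the 0.8 endpoint the
  unclamped map overshoots 100 by one floating-point ulp, which would
  silently fail `<= 100` interval tests.
* Tie-breaks are uniform: earliest composite, lowest code/class id,
  highest-priority lookup entry. Degenerate inputs (constant profiles,
  empty masks, zero-member classes, zones without lookup entries) are
  rejected or skipped with a note in the audit, never guessed at.
* `r_squared` is the squared Pearson correlation (identical to the R² of
  the simple linear fit with intercept); anomaly standardization uses the
  sample (n−1) standard deviation. Both choices are stated because the
  source leaves them open.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on 64×64
scenes (≈3,000 agricultural pixels, two crops, one zone) and smaller
variants, sizes chosen so the whole suite completes in seconds while still
exercising every stage end to end. Everything is seeded through R's
default generator via `withr::with_seed`; identical configuration and seed
reproduce bit-identical rasters on disk, which the tests verify by file
checksum.

## Known limitations

* The irrigation rule needs within-class contrast: uniformly irrigated
  classes are under-detected (see above). In humid regions where the
  irrigated/rainfed peak gap shrinks below the 0.15 separation, recall
  drops — the approach is built for water-limited zones.
* SCM is amplitude-invariant, so crop typing cannot distinguish crops that
  differ only in amplitude; the lookup-table height interval is the only
  amplitude-sensitive step.
* Sidecar georeferencing is self-describing but not embedded GeoTIFF
  tagging; GIS interoperability requires a one-line conversion with GDAL
  tooling outside this package.
* Reprojection, mosaicking and DEM-to-slope derivation are deliberately
  out of scope; inputs must arrive co-registered in one CRS.
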