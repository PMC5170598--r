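# irrimap

Maps irrigated agricultural area from water-year stacks of 16-day NDVI
composites (nominal 250 m pixels, 23 composites from June through May).
The intended users are remote-sensing hydrologists and agricultural water
managers who need annual, pixel-level irrigated/rainfed maps that can be
aggregated to administrative units and validated against ground-survey
statistics.

## Method

The pipeline has two stages.

**1. Crop typing by temporal-signature matching.** Analysis is restricted to
agricultural land cover on slopes of at most 20%, partitioned by
agroecological zone. On a deterministic 4 km lattice of training pixels,
seasonal descriptors are extracted from each NDVI profile: emergence and
senescence come from the cumulative NDVI departure
(`C_t = sum_{s<=t} (x_s - mean(x))`; emergence at the minimum of `C`,
senescence at the later maximum), and the seasonal peak NDVI is rescaled so
that 0.1–0.8 maps onto a 1–100 "height". A per-zone lookup table
(season, duration interval, height interval, applied in priority order)
labels each training pixel with a crop. Per-crop mean profiles become
end-member signatures, and every masked pixel is assigned to the crop whose
signature maximises the Spectral Correlation Mapper score — the Pearson-form
similarity

    SCM(x, r) = <x - x̄, r - r̄> / (||x - x̄|| · ||r - r̄||) ∈ [-1, 1],

with non-positive best scores never assigned (negative correlation is
excluded) and a configurable floor (default 0.5) rejecting weak matches.
The uncentered Spectral Angle Mapper (`sam_angle`) is included for
comparison.

**2. Decision-tree irrigation classification.** Within each crop class,
pixels are split into `n` condition subpools by ranked seasonal peak NDVI.
With `NDVI_imclass,i` the peak ceiling of subpool `i`:

    NDVI_mclass = (1/n) Σ_i NDVI_imclass,i        (class mean)
    NDVI_mp     = min_i NDVI_imclass,i            (stressed ceiling)
    MVCI        = (NDVI_mp - NDVI_mclass) / NDVI_mclass
    NDVI_irclass = MVCI · NDVI_mp + NDVI_mp

A pixel with seasonal peak `v` is labelled irrigated when
`v >= max(NDVI_irclass, 0.2)` and `v - NDVI_mp >= 0.15`. Each 250 m pixel
counts 6.25 ha; partial irrigation counts the whole pixel (binary product
semantics).

Diagnostics include space-time spiral curves (class mean RED/NIR
trajectories with a scalar separability), zonal/per-polygon aggregation,
RMSE and R² against survey tables, and first-difference / standardized
anomaly series. A deterministic synthetic-scene generator
(`scene_config()` / `generate_scene()` / `scenario_drought()`) produces
co-registered NDVI, RED/NIR, land-cover, slope and zone layers with known
crop and irrigation labels.

Raster I/O uses TIFF pixel data (via the `tiff` package) with a JSON
sidecar (`<file>.tif.aux.json`) carrying the grid (origin, pixel size, CRS
identifier, nodata), band dates and value encoding; `read_raster()` and
`write_raster()` round-trip all layer types (GDAL-style embedded GeoTIFF
tags are not written). Zone polygons are read from GeoJSON with
pixel-center membership.

## Worked example

```r
library(irrimap)

cfg <- scene_config(seed = 42)       # 64x64, 2 crops, boost 0.2, noise 0.02
scene <- generate_scene(cfg)
res <- run_pipeline(scene$ndvi, scene$lulc, scene$slope,
                    scene$zones, scene$lookup)
print(res$audit)
#> Irrigated-area pipeline audit
#>   masked agricultural pixels: 3060
#>   zone 1: 3060 pixels, 11 training samples, 1549 irrigated
#>     class 1 (Rice): n=1529, imclass [0.618, 0.804, 0.860], mclass 0.7609,
#>       mp 0.6181, MVCI -0.1877, irclass 0.5021, theta 0.5021, irrigated 764
#>     class 2 (Wheat): n=1531, imclass [0.612, 0.793, 0.857], mclass 0.7541,
#>       mp 0.6124, MVCI -0.1879, irclass 0.4974, theta 0.4974, irrigated 785
#>   total irrigated pixels: 1549

aggregate_area(res$irrigation)$total_ha
#> [1] 9681.25
```

Reading the audit: per crop class the three condition-subpool ceilings
(`imclass`) bracket the rainfed peak (~0.62 with noise) and the irrigated
peak (~0.8); their mean and minimum give MVCI ≈ −0.19 and a class threshold
θ ≈ 0.5, and the 0.15 separation clause then keeps rainfed pixels (peak ≈
0.62, gap ≈ 0) out while irrigated pixels (gap ≈ 0.2) are labelled 1. On
this scene the recovered labels match the generating truth for 99.8% of
agricultural pixels.

State-level validation against the packaged survey table:

```r
tab <- read_validation_table()
validation_stats(tab$des_mha, tab$modis_mha)
#> <validation_result> n=32  RMSE=0.8322  R2=0.9491
validation_stats(tab$des_mha, tab$iwmi_mha)
#> <validation_result> n=32  RMSE=7.9840  R2=0.7627
```

A command-line interface over the same functions lives in
`inst/cli/irrimap.R` (subcommands `simulate`, `stack`, `mask`, `train`,
`classify-crops`, `classify-irrigation`, `run`, `aggregate`, `validate`,
`stsc`, `anomalies`), driven by a single YAML/JSON config file; see
`inst/extdata/example_config.yaml`.

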