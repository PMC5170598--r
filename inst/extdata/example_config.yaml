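# Example pipeline configuration (paths relative to the working directory).
paths:
  ndvi: scene/ndvi.tif
  lulc: scene/lulc.tif
  slope: scene/slope.tif
  zones: scene/zones.tif
  lookup: scene/lookup.csv
  output_dir: out
water_year: "2000-01"
thresholds:
  slope_pct: 20
  min_irclass: 0.2
  min_separation: 0.15
  min_scm: 0.5
  sample_spacing_m: 4000
ag_codes: [1, 2, 3, 4]
seed: 1
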