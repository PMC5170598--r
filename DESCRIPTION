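Package: irrimap
Title: Irrigated-Area Mapping from NDVI Time Series by Crop-Signature
    Matching and Vegetation-Condition Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps irrigated agricultural area from water-year stacks of
    16-day NDVI composites. Crop types are classified by matching each
    pixel's temporal NDVI profile against end-member signatures with the
    Spectral Correlation Mapper (Pearson-form similarity), training
    samples being labelled from a crop calendar/lookup table via
    cumulative-NDVI-departure phenology. Irrigated pixels are then
    separated from rainfed ones with a decision-tree threshold derived
    from the class-level mean vegetation condition index (MVCI).
    Includes land-cover/slope masking, agroecological-zone partitioning,
    zonal area aggregation, space-time spiral-curve diagnostics,
    survey-table validation statistics (RMSE, R squared), a deterministic
    synthetic-scene generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
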