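Package: vpdp
Title: Voxel-Based Point Density Proxy Radiative Transfer for LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates forest LiDAR point clouds as inputs to a simplified
    canopy radiative transfer model in which per-voxel point counts stand in
    for leaf area density inside a Beer-Lambert attenuation law. Provides
    point cloud input/output and diagnostics (cross-sections, planar density
    maps), voxelization on a shared lattice, vertical density profiles,
    coverage gap ratio (CGR) profiles against a merged reference, column
    radiance simulation with Lambertian upward reflection, average-aggregation
    resampling to satellite pixel resolution, calibration of the attenuation
    coefficients against an observed near-infrared reflectance raster
    (Pearson correlation with sub-pixel shift search), repeated 70/30
    subsampling validation, and a synthetic forest/scan/satellite generator so
    the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
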