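Package: lagnav
Title: Homotopic BOLD Synchronization Lag and Connectome Navigation Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates interhemispheric (homotopic) synchronization lag from
    region-level resting-state BOLD time series via shifted cross-correlation
    with sub-sample parabolic interpolation, and relates it to the
    communication architecture of weighted structural connectomes.
    Implements shortest-path and greedy spatial navigation routing on
    length-remapped streamline-count networks, communication efficiency and
    its area under the curve over proportional density thresholds,
    navigation distance, lesion-geometry measures, and the cohort-level
    statistical analysis (group contrasts, lag-distance and lag-efficiency
    correlations, variance partitioning, false discovery rate control).
    Ships a synthetic-cohort generator that plants sub-TR homotopic lags in
    band-limited signals, spatially embedded connectomes, and focal lesions,
    so the full pipeline runs end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
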