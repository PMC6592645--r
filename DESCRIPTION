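Package: g1waves
Title: Quantitative Blueprints of G1 Cyclin Waves from Pooled Western Blots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for time courses of the budding-yeast G1
    cyclins (Cln1-3, Pcl1/2/7) and the START landmarks Clb5 and Sic1 measured
    by western blot on pooled tagged strains. Implements the full chain from
    raw band densitometry to normalized cyclin "wave" blueprints: correction
    of strain-mixing proportions, loading-control normalization,
    relativization to the maximum blot signal, and replicate aggregation to
    mean +/- SEM. Locates START as the interpolated Sic1/Clb5 crossing,
    integrates per-cyclin area under the curve from release to START, and
    summarises Cln- and Pcl-family contributions. Also estimates culture
    duplication times from OD660 growth series by log2-linear regression over
    an automatically selected exponential window and compares groups with an
    exact (full-enumeration) Mann-Whitney U test. A synthetic-data module
    generates pulse-shaped cyclin waves, the pooled-blot observation model and
    growth curves with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
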