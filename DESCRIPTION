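Package: azpoints
Title: Spatial Analysis of Immunogold Point Patterns in Presynaptic Active Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of gold-particle point patterns from
    SDS-digested freeze-fracture replica labeling (SDS-FRL) of presynaptic
    active zones. Provides polygonal window geometry and particle-table I/O,
    nearest-neighbour-distance statistics with a Monte-Carlo complete-spatial-
    randomness null and paired testing across active zones, a kernel pair-
    correlation function g(r) with isotropic edge correction, DBSCAN and
    fixed-radius cluster detection with the mean-NND + 2SD epsilon rule, a
    centre-periphery index, and the density/labeling-efficiency calibration
    chain that converts particle densities into channel numbers. A synthetic-
    data module generates complete-spatial-randomness, clustered, and
    channel/vesicle topography scenes (random, perimeter-release, one-to-one,
    exclusion-zone) plus a virtual-labeling model (binomial detection,
    localisation jitter, Poisson background, antibody-aggregation clumps) so
    the whole pipeline runs against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    spatstat.geom,
    spatstat.explore
Config/testthat/edition: 3
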