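Package: gridtag
Title: Grid-Filter Hidden Markov Model Geolocation for Pop-Up Archival Tags
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Maintainer
Maintainer: Package Maintainer <maintainer@example.org>
Description: Daily-scale geolocation of pop-up satellite archival tag (PSAT)
    deployments by a hidden Markov model on a discretized ocean grid.
    Sunrise/sunset times and sea-surface temperature are combined with a
    mass-conserving advection-diffusion movement model solved with zero-flux
    boundary conditions along coastlines, a forward filter anchored at the
    deployment position, a backward filter anchored at the pop-up position,
    and a two-filter smoother. Includes set-membership cleaning of solar
    event times, pooling of smoothed daily posteriors into utilization
    distributions with highest-posterior-density regions, point-coverage
    validation against independent tagging records, and a synthetic
    ocean/track/tag simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
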