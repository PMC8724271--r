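Package: aavrange
Title: Effective Paracrine Range and Minimum AAV Infection Rate Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative chain from single-cell cardiomyocyte morphometry to
    adeno-associated virus (AAV) dosing for paracrine-mediated (non-cell-autonomous)
    gene therapy. Estimates the effective paracrine range of an AAV-delivered factor
    as the intersection of a distance-to-infected-cell versus cell-area regression
    with the lower confidence bound of the hypertrophic cell-area mean, then converts
    that range into a theoretical minimum infection rate with a three-dimensional
    cuboid-lattice tissue coverage model. Includes a calibrated synthetic morphometry
    generator, per-animal infection-rate and group-comparison statistics, and an
    end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
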