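Package: brbud
Title: Movement-Based Utilization Distributions from Biased Random Bridges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates animal utilization distributions (UDs) from serially
    correlated GPS relocations and activity data using simplified (isotropic)
    biased random bridges computed through movement-based kernel density
    estimation (MKDE). Provides trajectory ingestion and segment filtering,
    diffusion-coefficient and habitat-specific drift-speed estimation from
    relocation triplets, variable-bandwidth kernel UD rasters with
    cumulative-frequency isopleths, habitat availability/use/preference
    tables, and a seeded random-walk simulator (Brownian, biased, correlated)
    with endpoint-conditioned bridge ensembles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
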