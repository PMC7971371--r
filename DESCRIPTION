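Package: chwplan
Title: Coverage and Capacity Planning for Community Health Worker Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Time-use planning model for community health worker (CHW)
    programs. Sizes annual target populations from demographic fractions and
    event rates, accounts service time demanded by an intervention package
    against service time supplied by CHW cadres after ancillary time
    (administration, training, travel, campaigns), and answers three policy
    questions: how many CHWs are needed to reach targeted coverage, what
    coverage a fixed workforce can achieve, and how scenario edits
    (dropping or rescaling interventions, changing headcounts) shift the
    coverage-capacity balance. Scenarios are immutable YAML-serializable
    values; results export as tidy CSV tables and figure data. Ships
    fixtures for the published Rwanda and Zanzibar program analyses and a
    seeded synthetic-scenario generator for property testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
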