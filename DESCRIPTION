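Package: pghdflow
Title: Standards-Based Workflows for Patient-Generated Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-testable workflow engine for patient-generated health
    data (PGHD) exchanged as HL7 FHIR R4 resources. Practitioners dispatch
    instrument requests (ServiceRequest), patients complete sessions --
    static questionnaires with skip logic, computer-adaptive surveys against
    a bundled item-response-theory service, connected-device imports, and
    active-task results -- and the outcomes are encoded, validated for
    structure and questionnaire concordance, bundled with subject and
    requester tags, and submitted to an in-memory mock FHIR store. All
    fixtures are generated deterministically; no network access is needed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    lubridate,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
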