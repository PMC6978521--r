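# Coding map: the editable binding between instrument categories / result
# kinds and terminology codes. Extension and coding URLs are configuration,
# not constants — registries drift, and the source framework cites HL7
# extensions by reference only. Defaults use LOINC for activity and vital
# signs and a project-local system for active tasks.

project_system <- "urn:pghdflow:active-task"

#' Default coding map
#'
#' One row per result kind: the instrument category it belongs to, the
#' terminology binding (`system`, `code`, `display`), the FHIR result
#' resource types the kind encodes to (per the instrument conformance
#' matrix), and the fixed unit where the result carries a quantity.
#'
#' @return A tibble with columns `kind`, `category`, `system`, `code`,
#'   `display`, `result_types` (comma-separated resource types), `unit`.
#' @export
default_coding_map <- function() {
  tibble::tribble(
    ~kind, ~category, ~system, ~code, ~display, ~result_types, ~unit,
    "survey_static", "survey_static", "urn:pghdflow:survey", "static-survey",
      "Static survey", "QuestionnaireResponse", NA,
    "survey_adaptive", "survey_adaptive", "urn:pghdflow:survey", "adaptive-survey",
      "Adaptive survey", "QuestionnaireResponse", NA,
    "step_count", "device_recorded", "http://loinc.org", "55423-8",
      "Number of steps in unspecified time pedometer", "Observation", "steps",
    "blood_pressure", "device_recorded", "http://loinc.org", "85354-9",
      "Blood pressure panel with all children optional", "Observation", "mmHg",
    "range_of_motion", "active_task", project_system, "range-of-motion",
      "Range of motion (knee, shoulder)", "Observation", "deg",
    "tapping_speed", "active_task", project_system, "tapping-speed",
      "Tapping speed", "Observation,DocumentReference", "taps/s",
    "peg_hole", "active_task", project_system, "nine-peg-hole",
      "9 peg hole test", "Observation,DocumentReference", "s",
    "paced_addition", "active_task", project_system, "paced-serial-addition",
      "Paced serial addition test", "Observation,DocumentReference", "{score}",
    "tower_of_hanoi", "active_task", project_system, "tower-of-hanoi",
      "Tower of Hanoi", "Observation", NA,
    "stroop", "active_task", project_system, "stroop-test",
      "Stroop test", "Observation", "s",
    "spatial_span", "active_task", project_system, "spatial-memory-span",
      "Spatial memory span", "Observation", "{score}",
    "amsler_grid", "active_task", project_system, "amsler-grid",
      "Amsler grid", "Observation,Media", NA,
    "health_record", "device_recorded", "urn:pghdflow:health-record", "fhir-dstu2",
      "Phone health-record export (FHIR)", "Observation", NA
  )
}

#' Workflow configuration: extension URLs and LOINC component codes
#'
#' @return Named list of the configurable URL/code bindings: the adaptive
#'   questionnaire extension (carries the next-question service endpoint),
#'   the questionnaire-reference extension on ServiceRequest, the
#'   report-basis linkage, the adaptive session identifier system, the
#'   score extension, and the systolic/diastolic component codes.
#' @export
pghd_config <- function() {
  list(
    adaptive_extension_url = "http://hl7.org/fhir/StructureDefinition/questionnaire-adaptive",
    questionnaire_extension_url = "http://hl7.org/fhir/StructureDefinition/servicerequest-questionnaire",
    session_id_system = "urn:pghdflow:adaptive-session",
    score_extension_url = "urn:pghdflow:score-tscore",
    systolic = list(system = "http://loinc.org", code = "8480-6",
                    display = "Systolic blood pressure"),
    diastolic = list(system = "http://loinc.org", code = "8462-4",
                     display = "Diastolic blood pressure"),
    ucum = "http://unitsofmeasure.org"
  )
}

#' Read a coding map from its JSON configuration file
#'
#' The schema matches [default_coding_map()]: a JSON array of objects with
#' keys `kind`, `category`, `system`, `code`, `display`, `result_types`,
#' `unit` (nullable). The package ships the default at
#' `system.file("extdata", "coding-map.json", package = "pghdflow")`.
#'
#' @param path Path to the JSON file.
#' @return A coding-map tibble.
#' @export
read_coding_map <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(rows)
  need <- c("kind", "category", "system", "code", "display", "result_types", "unit")
  if (!all(need %in% names(out))) {
    stop(pghd_error("config", "coding map file missing required columns"))
  }
  out[need]
}

# category for a (system, code) pair, NA if unmapped
lookup_coding <- function(map, system, code) {
  hit <- map[map$system == system & map$code == code, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  as.list(hit[1, ])
}
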