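#' @title Encoding raw task results as FHIR resources
#' @description
#' Every instrument kind in the conformance matrix has an encoder that turns
#' a typed raw result into its FHIR result resource(s): a step count becomes
#' one Observation with an integer quantity; a blood-pressure reading an
#' Observation with systolic and diastolic components (mmHg); range of
#' motion an angle quantity in degrees; Stroop a duration in seconds;
#' Tower of Hanoi a boolean; spatial span an integer score; tapping, peg
#' hole and paced addition an Observation plus a DocumentReference holding
#' the raw record; the Amsler grid an Observation plus a Media image; and a
#' phone health-record export is mapped from DSTU2 to R4. Units are fixed
#' per kind — mismatches are errors, never conversions.
#' @name encoding
NULL

#' Construct a typed raw task result
#'
#' @param kind Result kind token (a row of the coding map), e.g.
#'   `"step_count"`, `"blood_pressure"`, `"tower_of_hanoi"`.
#' @param payload Typed value(s); shape depends on `kind`: a count, a list
#'   `list(systolic=, diastolic=)` in mmHg, an angle in `[0, 360)` degrees,
#'   a duration in seconds, a boolean, a score, a list
#'   `list(finding=, image=)` with a base64 image, or a foreign DSTU2
#'   resource for `health_record`.
#' @param effective_time Timestamp of the measurement.
#' @param unit Optional unit token; must equal the kind's fixed unit.
#' @return A `task_result`.
#' @export
task_result <- function(kind, payload, effective_time = Sys.time(),
                        unit = NULL) {
  map <- default_coding_map()
  row <- map[map$kind == kind, , drop = FALSE]
  if (nrow(row) == 0) {
    stop(pghd_error("encoding", paste0("unmapped result kind: ", kind)))
  }
  if (!is.null(unit) && !is.na(row$unit) && !identical(unit, row$unit)) {
    stop(pghd_error("type", paste0(kind, " results are fixed to unit ",
                                   row$unit, ", got ", unit)))
  }
  validate_payload(kind, payload)
  structure(list(kind = kind, category = row$category, payload = payload,
                 effective_time = effective_time),
            class = "task_result")
}

validate_payload <- function(kind, payload) {
  bad <- function(msg) stop(pghd_error("type", paste0(kind, ": ", msg)))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  switch(kind,
    step_count = if (!num1(payload) || payload < 0 ||
                     abs(payload - round(payload)) > 1e-9)
      bad("payload must be a non-negative integer count"),
    blood_pressure = {
      if (!is.list(payload) || !num1(payload$systolic) ||
          !num1(payload$diastolic)) bad("payload must carry systolic and diastolic")
      if (payload$systolic <= 0 || payload$diastolic <= 0)
        bad("pressures must be positive")
    },
    range_of_motion = if (!num1(payload) || payload < 0 || payload >= 360)
      bad("angle must lie in [0, 360) degrees"),
    tapping_speed = if (!num1(payload) || payload < 0)
      bad("payload must be a non-negative tap rate"),
    peg_hole = ,
    stroop = if (!num1(payload) || payload < 0)
      bad("payload must be a non-negative duration in seconds"),
    paced_addition = ,
    spatial_span = if (!num1(payload) || payload < 0)
      bad("payload must be a non-negative score"),
    tower_of_hanoi = if (!is.logical(payload) || length(payload) != 1 ||
                         is.na(payload)) bad("payload must be a boolean"),
    amsler_grid = if (!is.list(payload) || is.null(payload$image))
      bad("payload must carry an image"),
    health_record = if (!is.list(payload) || is.null(payload$resourceType))
      bad("payload must be a foreign FHIR resource"),
    bad("unknown kind")
  )
  invisible(TRUE)
}

#' @export
print.task_result <- function(x, ...) {
  cat("<task_result> ", x$kind, " (", x$category, ") @ ",
      format(x$effective_time), "\n", sep = "")
  invisible(x)
}

#' Encode a raw task result into its FHIR result resource(s)
#'
#' @param result A [task_result()].
#' @param coding_map Coding map tibble binding kinds to codes and units.
#' @return List of `fhir_resource` trees, with types exactly as the
#'   conformance matrix prescribes for the kind. All outputs pass
#'   [fhir_check_structure()].
#' @examples
#' encode_result(task_result("step_count", 4200))[[1]]$valueQuantity$value
#' @export
encode_result <- function(result, coding_map = default_coding_map()) {
  stopifnot(inherits(result, "task_result"))
  row <- coding_map[coding_map$kind == result$kind, , drop = FALSE]
  if (nrow(row) == 0) {
    stop(pghd_error("encoding", paste0("result kind not in coding map: ",
                                       result$kind)))
  }
  cfg <- pghd_config()
  when <- format(as.POSIXct(result$effective_time, tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%SZ")
  code_cc <- list(coding = list(list(system = row$system, code = row$code,
                                     display = row$display)))
  obs <- list(resourceType = "Observation", status = "final", code = code_cc,
              effectiveDateTime = when)
  qty <- function(value, unit) list(value = as.double(value), unit = unit,
                                    system = cfg$ucum, code = unit)
  resources <- switch(result$kind,
    step_count = {
      obs$valueQuantity <- qty(result$payload, row$unit)
      list(obs)
    },
    blood_pressure = {
      obs$component <- list(
        list(code = list(coding = list(cfg$systolic)),
             valueQuantity = qty(result$payload$systolic, row$unit)),
        list(code = list(coding = list(cfg$diastolic)),
             valueQuantity = qty(result$payload$diastolic, row$unit)))
      list(obs)
    },
    range_of_motion = {
      obs$valueQuantity <- qty(result$payload, row$unit)
      list(obs)
    },
    tapping_speed = ,
    peg_hole = ,
    paced_addition = {
      obs$valueQuantity <- qty(result$payload, row$unit)
      list(obs, raw_document(result, row, when))
    },
    tower_of_hanoi = {
      obs$valueBoolean <- result$payload
      list(obs)
    },
    stroop = {
      obs$valueQuantity <- qty(result$payload, row$unit)
      list(obs)
    },
    spatial_span = {
      obs$valueInteger <- as.double(round(result$payload))
      list(obs)
    },
    amsler_grid = {
      obs$valueBoolean <- isTRUE(result$payload$finding)
      media <- list(resourceType = "Media", status = "completed",
                    createdDateTime = when,
                    content = list(contentType = "image/png",
                                   data = result$payload$image,
                                   title = "Amsler grid capture"))
      list(obs, media)
    },
    health_record = list(unclass(map_dstu2_to_r4(result$payload))),
    stop(pghd_error("encoding", paste0("no encoder for kind ", result$kind)))
  )
  purrr::map(resources, as_fhir_resource)
}

raw_document <- function(result, row, when) {
  raw_json <- jsonlite::toJSON(list(kind = result$kind,
                                    payload = result$payload,
                                    effective = when),
                               auto_unbox = TRUE, digits = NA)
  list(resourceType = "DocumentReference", status = "current",
       type = list(coding = list(list(system = row$system, code = row$code,
                                      display = paste0(row$display, " raw data")))),
       date = when,
       content = list(list(attachment = list(
         contentType = "application/json",
         data = jsonlite::base64_enc(as.character(raw_json)),
         title = paste0(result$kind, " raw record")))))
}

#' A synthetic connected-device cloud adapter
#'
#' Emulates a blood-pressure device vendor's cloud export: holds records of
#' `{systolic, diastolic, timestamp}` behind a token check, the shape a
#' patient-mediated fetch sees.
#'
#' @param records Tibble/data frame with columns `systolic`, `diastolic`,
#'   `timestamp`.
#' @param token The token the adapter expects.
#' @return A `device_adapter`.
#' @export
device_adapter <- function(records, token = "device-token") {
  stopifnot(all(c("systolic", "diastolic", "timestamp") %in% names(records)))
  structure(list(records = tibble::as_tibble(records), token = token),
            class = "device_adapter")
}

#' Generate a deterministic synthetic blood-pressure export
#'
#' @param n Number of records.
#' @param start First day of the export window.
#' @param seed RNG seed.
#' @param token Adapter token.
#' @return A [device_adapter()] with one record per day from `start`.
#' @export
synthetic_bp_export <- function(n = 7, start = as.Date("2020-03-01"),
                                seed = 1L, token = "device-token") {
  recs <- withr::with_seed(seed, tibble::tibble(
    systolic = round(stats::rnorm(n, 125, 8)),
    diastolic = round(stats::rnorm(n, 80, 6)),
    timestamp = format(as.POSIXct(paste0(start + seq_len(n) - 1, " 08:30:00"),
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  ))
  recs$systolic <- pmax(recs$systolic, 70)
  recs$diastolic <- pmax(recs$diastolic, 40)
  device_adapter(recs, token)
}

#' Fetch vitals from an external repository adapter
#'
#' One blood-pressure [task_result()] per record inside the window,
#' timestamps preserved.
#'
#' @param adapter A [device_adapter()].
#' @param patient_token Opaque credential presented to the adapter.
#' @param window Length-2 date vector `(from, to)`, inclusive.
#' @return List of `task_result`s.
#' @export
fetch_external_vitals <- function(adapter, patient_token, window) {
  stopifnot(inherits(adapter, "device_adapter"))
  if (!identical(patient_token, adapter$token)) {
    stop(pghd_error("transport", "device adapter rejected the credentials"))
  }
  window <- as.Date(window)
  dates <- as.Date(substr(adapter$records$timestamp, 1, 10))
  keep <- adapter$records[dates >= window[1] & dates <= window[2], ,
                          drop = FALSE]
  purrr::pmap(keep, function(systolic, diastolic, timestamp) {
    task_result("blood_pressure",
                list(systolic = systolic, diastolic = diastolic),
                effective_time = as.POSIXct(timestamp, tz = "UTC",
                                            format = "%Y-%m-%dT%H:%M:%SZ"))
  })
}

#' Map a DSTU2 Observation to R4
#'
#' Element-wise translation per the published version delta, restricted to
#' Observation (a deliberate subset of the phone health-record import):
#' `category` grows from a single CodeableConcept to an array, `comment`
#' becomes `note[].text`, and value/component elements carry over
#' bit-exact. The output passes R4 structural validation.
#'
#' @param foreign A DSTU2 resource element tree (parsed JSON).
#' @return An R4 `fhir_resource`.
#' @export
map_dstu2_to_r4 <- function(foreign) {
  if (is.character(foreign)) {
    foreign <- jsonlite::fromJSON(foreign, simplifyVector = FALSE)
  }
  rt <- foreign$resourceType %||% "(none)"
  if (!identical(rt, "Observation")) {
    stop(pghd_error("unsupported-mapping",
                    paste0("DSTU2 mapping supports Observation only, got ", rt)))
  }
  foreign <- normalize_numbers(foreign)
  out <- list(resourceType = "Observation")
  for (k in names(foreign)) {
    v <- foreign[[k]]
    if (k %in% c("resourceType")) next
    if (k == "category") {           # 0..1 in DSTU2 -> 0..* in R4
      out$category <- list(v)
    } else if (k == "comment") {     # string -> Annotation list
      out$note <- list(list(text = v))
    } else if (k %in% c("related", "reliability")) {
      next                           # no direct R4 counterpart in subset
    } else {
      out[[k]] <- v
    }
  }
  as_fhir_resource(out)
}

#' Generate a deterministic synthetic DSTU2 Observation corpus
#'
#' Emulates a phone health-record export (the DSTU2-speaking source):
#' quantity-valued vitals with `category` as a single CodeableConcept and a
#' free-text `comment`, the two elements whose shape changed in R4.
#'
#' @param n Number of observations.
#' @param seed RNG seed.
#' @return List of DSTU2 element trees (plain lists, not `fhir_resource`).
#' @export
synthetic_dstu2_observations <- function(n = 10, seed = 1L) {
  withr::with_seed(seed, purrr::map(seq_len(n), function(i) {
    list(
      resourceType = "Observation",
      id = sprintf("dstu2-obs-%02d", i),
      status = "final",
      category = list(coding = list(list(
        system = "http://hl7.org/fhir/observation-category",
        code = "vital-signs"))),
      code = list(coding = list(list(system = "http://loinc.org",
                                     code = "29463-7",
                                     display = "Body weight"))),
      effectiveDateTime = format(as.Date("2019-06-01") + i, "%Y-%m-%d"),
      valueQuantity = list(value = round(stats::runif(1, 50, 95), 1),
                           unit = "kg", system = "http://unitsofmeasure.org",
                           code = "kg"),
      comment = sprintf("self-measured, reading %d", i)
    )
  }))
}
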