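now <- as.POSIXct("2020-03-02 09:00:00", tz = "UTC")

test_that("the encoder matrix reproduces the conformance table row by row", {
  # table-driven: each kind's emitted resource types must equal the matrix
  cases <- list(
    step_count = task_result("step_count", 4200, now),
    blood_pressure = task_result("blood_pressure",
                                 list(systolic = 128, diastolic = 82), now),
    range_of_motion = task_result("range_of_motion", 117.5, now),
    tapping_speed = task_result("tapping_speed", 4.2, now),
    peg_hole = task_result("peg_hole", 31.8, now),
    paced_addition = task_result("paced_addition", 42, now),
    tower_of_hanoi = task_result("tower_of_hanoi", TRUE, now),
    stroop = task_result("stroop", 1.25, now),
    spatial_span = task_result("spatial_span", 6, now),
    amsler_grid = task_result("amsler_grid",
                              list(finding = TRUE,
                                   image = jsonlite::base64_enc(charToRaw("png"))),
                              now)
  )
  map <- default_coding_map()
  covered <- character()
  for (kind in names(cases)) {
    out <- encode_result(cases[[kind]])
    types <- vapply(out, `[[`, "", "resourceType")
    want <- strsplit(map$result_types[map$kind == kind], ",")[[1]]
    expect_identical(types, want, label = kind)
    for (r in out) {
      iss <- fhir_check_structure(r)
      expect_identical(sum(iss$severity == "error"), 0L,
                       label = paste(kind, r$resourceType))
    }
    covered <- c(covered, kind)
  }
  # every device/active-task row of the matrix has an encoder (health_record
  # goes through the DSTU2 mapper, exercised below)
  rows <- map$kind[map$category %in% c("device_recorded", "active_task")]
  expect_identical(setdiff(rows, c(covered, "health_record")), character(0))
})

test_that("frozen value encodings match the matrix semantics", {
  obs <- encode_result(task_result("step_count", 4200, now))[[1]]
  expect_identical(obs$valueQuantity$value, 4200)
  expect_identical(obs$valueQuantity$unit, "steps")
  expect_identical(obs$code$coding[[1]]$code, "55423-8")

  hanoi <- encode_result(task_result("tower_of_hanoi", TRUE, now))[[1]]
  expect_identical(hanoi$valueBoolean, TRUE)

  bp <- encode_result(task_result("blood_pressure",
                                  list(systolic = 131, diastolic = 79),
                                  now))[[1]]
  comps <- purrr::map_chr(bp$component, function(c) c$code$coding[[1]]$code)
  expect_identical(comps, c("8480-6", "8462-4"))
  expect_identical(purrr::map_dbl(bp$component,
                                  function(c) c$valueQuantity$value),
                   c(131, 79))
  expect_identical(bp$component[[1]]$valueQuantity$unit, "mmHg")

  amsler <- encode_result(task_result("amsler_grid",
                                      list(finding = FALSE,
                                           image = jsonlite::base64_enc(
                                             charToRaw("img"))), now))
  expect_identical(vapply(amsler, `[[`, "", "resourceType"),
                   c("Observation", "Media"))
  expect_identical(amsler[[2]]$content$contentType, "image/png")

  taps <- encode_result(task_result("tapping_speed", 4.5, now))
  expect_identical(taps[[2]]$resourceType, "DocumentReference")
  expect_match(taps[[2]]$content[[1]]$attachment$contentType, "json")
})

test_that("typed payload validation refuses mismatches, units are fixed", {
  expect_error(task_result("step_count", -1), class = "pghd_error_type")
  expect_error(task_result("tower_of_hanoi", "yes"), class = "pghd_error_type")
  expect_error(task_result("range_of_motion", 400), class = "pghd_error_type")
  expect_error(task_result("blood_pressure",
                           list(systolic = -120, diastolic = 80)),
               class = "pghd_error_type")
  expect_error(task_result("step_count", 100, unit = "km"),
               class = "pghd_error_type")
  expect_error(task_result("no_such_kind", 1), class = "pghd_error_encoding")
})

test_that("device-cloud fetch yields one result per record in the window", {
  adapter <- synthetic_bp_export(n = 9, start = as.Date("2020-02-20"),
                                 seed = 2)
  got <- fetch_external_vitals(adapter, "device-token",
                               window = c("2020-02-22", "2020-02-26"))
  expect_length(got, 5)
  expect_true(all(vapply(got, function(r) r$kind, "") == "blood_pressure"))
  # timestamps preserved through encoding
  obs <- encode_result(got[[1]])[[1]]
  expect_identical(obs$effectiveDateTime, adapter$records$timestamp[3])
  expect_length(obs$component, 2)

  expect_length(fetch_external_vitals(adapter, "device-token",
                                      window = c("2021-01-01", "2021-01-02")),
                0)
  expect_error(fetch_external_vitals(adapter, "wrong-token",
                                     window = c("2020-02-22", "2020-02-26")),
               class = "pghd_error_transport")
})

test_that("DSTU2 observations map element-wise into valid R4", {
  d2 <- synthetic_dstu2_observations(1, seed = 3)[[1]]
  r4 <- map_dstu2_to_r4(d2)
  expect_identical(r4$valueQuantity$value, d2$valueQuantity$value) # bit-exact
  expect_identical(r4$category, list(d2$category))   # 0..1 -> 0..*
  expect_identical(r4$note[[1]]$text, d2$comment)    # comment -> note[].text
  expect_null(r4$comment)

  expect_error(map_dstu2_to_r4(list(resourceType = "MedicationOrder")),
               class = "pghd_error_unsupported-mapping")

  corpus <- synthetic_dstu2_observations(10, seed = 12)
  mapped <- purrr::map(corpus, map_dstu2_to_r4)
  expect_length(mapped, 10)
  n_err <- sum(purrr::map_int(mapped, function(r) {
    sum(fhir_check_structure(r)$severity == "error")
  }))
  expect_identical(n_err, 0L)

  # the shipped sample file is mappable too
  sample_path <- system.file("extdata", "sample-dstu2-observation.synthetic.json",
                             package = "pghdflow")
  r4s <- map_dstu2_to_r4(paste(readLines(sample_path), collapse = "\n"))
  expect_identical(sum(fhir_check_structure(r4s)$severity == "error"), 0L)
})
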