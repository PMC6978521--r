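now <- as.POSIXct("2020-03-02 09:00:00", tz = "UTC")

make_request <- function(store, n_instruments = 1, seed = 5L) {
  fx <- seed_example_repository(store, seed = seed)
  patient <- paste0("Patient/", fx$patients[[1]][["id"]])
  instruments <- list_instruments(store)
  reqs <- create_requests(patient, "Practitioner/d1",
                          instruments[seq_len(n_instruments), ],
                          pghd_schedule("instant"), now = now, store = store)
  list(fx = fx, patient = patient, instruments = instruments, reqs = reqs)
}

test_that("assembled bundles tag every entry with subject and request basis", {
  st <- mock_store()
  w <- make_request(st)
  req <- w$reqs[[1]]

  obs <- encode_result(task_result("step_count", 4200, now))
  rep1 <- assemble_report(obs, req, date = as.Date(now))
  expect_identical(rep1$bundle$type, "transaction")
  expect_length(rep1$bundle$entry, 1)
  entry <- rep1$bundle$entry[[1]]
  expect_identical(entry$resource$subject$reference, w$patient)
  expect_identical(entry$resource$basedOn[[1]]$reference,
                   paste0("ServiceRequest/", req$id))
  expect_identical(entry$resource$performer[[1]]$reference, "Practitioner/d1")
  expect_identical(nrow(validate_report(rep1)), 0L)

  # mixed content: QuestionnaireResponse + 2 Observations, uniform subject
  q <- w$instruments$resource[[which(w$instruments$category == "survey_static")[1]]]
  s <- build_session(static_instrument(q), req$id)
  run_session_script(s, synth_answer_script(q, seed = 1))
  qr <- finalize_static(s, authored = now)
  more <- c(list(qr), obs,
            encode_result(task_result("stroop", 1.1, now)))
  rep3 <- assemble_report(more, req, date = as.Date(now))
  expect_length(rep3$bundle$entry, 3)
  subjects <- vapply(rep3$bundle$entry,
                     function(e) e$resource$subject$reference, "")
  expect_identical(unique(subjects), w$patient)
  expect_identical(nrow(validate_report(rep3)), 0L)

  # a resource already owned by a different subject cannot be re-tagged
  foreign <- unclass(obs[[1]])
  foreign$subject <- list(reference = "Patient/someone-else")
  expect_error(assemble_report(list(foreign), req),
               class = "pghd_error_tagging")
  expect_error(assemble_report(list(), req), class = "pghd_error_precondition")
})

test_that("consent gates every store interaction", {
  st <- mock_store()
  w <- make_request(st)
  obs <- encode_result(task_result("step_count", 512, now))
  rep <- assemble_report(obs, w$reqs[[1]], date = as.Date(now))

  log_before <- nrow(store_log(st))
  declined <- submit_report(rep, st, consent = FALSE)
  expect_identical(declined$outcome, "declined")
  expect_false(declined$submitted)
  expect_identical(nrow(store_log(st)), log_before)   # zero interactions

  granted <- submit_report(rep, st, consent = TRUE)
  expect_identical(granted$outcome, "submitted")
  expect_length(granted$assigned, 1)
  # conservation: patient search returns exactly the submitted set
  found <- store_interact(st, "search", "Observation",
                          params = list(patient = w$patient))
  expect_identical(length(found$entry), 1L)
  expect_identical(found$entry[[1]]$resource$valueQuantity$value, 512)

  again <- submit_report(granted, st, consent = TRUE)
  expect_identical(again$outcome, "already-submitted")
  found2 <- store_interact(st, "search", "Observation",
                           params = list(patient = w$patient))
  expect_identical(length(found2$entry), 1L)          # no duplicates
})

test_that("each concordance fault class is detected on its minimal fixture", {
  q <- tiny_questionnaire(list(
    q_item("a", "boolean", required = TRUE),
    q_item("b", "integer", enableWhen = ew("a", "=", TRUE)),
    q_item("c", "choice", answerOption = list(
      list(valueCoding = list(system = "urn:t", code = "c1", display = "C1")),
      list(valueCoding = list(system = "urn:t", code = "c2", display = "C2"))))
  ), id = "q-mut")

  base_qr <- function() {
    s <- build_session(static_instrument(q), "r")
    run_session_script(s, list(a = TRUE, b = 4,
                               c = list(system = "urn:t", code = "c1")))
    unclass(finalize_static(s, authored = now))
  }
  expect_identical(nrow(validate_response(as_fhir_resource(base_qr()), q)), 0L)

  mutate_qr <- function(f) { x <- base_qr(); as_fhir_resource(f(x)) }
  cases <- list(
    `unknown-linkId` = function(x) {
      x$item[[2]]$linkId <- "zz"; x
    },
    `missing-required` = function(x) {
      x$item <- x$item[-c(1, 2)]; x  # drops required 'a' (and its dependant)
    },
    `type-mismatch` = function(x) {
      x$item[[2]]$answer[[1]] <- list(valueString = "four"); x
    },
    `disabled-item-answered` = function(x) {
      x$item[[1]]$answer[[1]] <- list(valueBoolean = FALSE); x
    },
    `wrong-questionnaire` = function(x) {
      x$questionnaire <- "urn:test:other"; x
    },
    `duplicate-linkId` = function(x) {
      x$item <- c(x$item, x$item[2]); x
    }
  )
  for (code in names(cases)) {
    issues <- validate_response(mutate_qr(cases[[code]]), q)
    expect_true(code %in% issues$code,
                label = paste0(code, " detected (got: ",
                               paste(issues$code, collapse = ","), ")"))
    # the seeded fault dominates: no unrelated fault classes fire
    unrelated <- setdiff(issues$code, switch(code,
      `missing-required` = code,
      `disabled-item-answered` = c(code, "missing-required"),
      `type-mismatch` = code,
      code))
    expect_identical(unrelated, character(0), label = code)
  }

  # choice answers outside the offered options are type mismatches
  off_option <- mutate_qr(function(x) {
    x$item[[3]]$answer[[1]]$valueCoding$code <- "c9"; x
  })
  expect_true("type-mismatch" %in% validate_response(off_option, q)$code)
})

test_that("no false positives on conformant generated response pairs", {
  n_bad <- 0L
  for (seed in 1:50) {
    fx <- generate_fixtures(fixture_spec(seed = seed, n_static_q = 1,
                                         skip_logic_density = 0.4))
    q <- fx$questionnaires[[1]]
    s <- build_session(static_instrument(q), "r")
    run_session_script(s, synth_answer_script(q, seed = seed + 1000))
    qr <- finalize_static(s, authored = now)
    n_bad <- n_bad + nrow(validate_response(qr, q))
  }
  expect_identical(n_bad, 0L)
})

test_that("report-level validation spots mixed subjects and missing bases", {
  st <- mock_store()
  w <- make_request(st)
  obs <- encode_result(task_result("step_count", 100, now))
  rep <- assemble_report(obs, w$reqs[[1]], date = as.Date(now))

  broken <- rep
  broken$bundle$entry[[1]]$resource$subject$reference <- "Patient/intruder"
  iss <- validate_report(broken)
  expect_identical(iss$code, "wrong-subject")

  broken2 <- rep
  broken2$bundle$entry[[1]]$resource$basedOn <- NULL
  expect_identical(validate_report(broken2)$code, "missing-request-basis")
})
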