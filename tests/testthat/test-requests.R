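test_that("slot enumeration matches the frozen calendar examples", {
  # 28-day window / 7-day slots, enumerated by the day-walk oracle
  wk <- compute_slots(pghd_schedule("weekly", "2020-01-01", "2020-01-28"))
  expect_identical(nrow(wk), 4L)
  expect_identical(wk$start, as.Date(c("2020-01-01", "2020-01-08",
                                       "2020-01-15", "2020-01-22")))
  expect_identical(wk$end, as.Date(c("2020-01-07", "2020-01-14",
                                     "2020-01-21", "2020-01-28")))

  mo <- compute_slots(pghd_schedule("monthly", "2020-01-15", "2020-03-14"))
  expect_identical(nrow(mo), 2L)
  expect_identical(mo$start, as.Date(c("2020-01-15", "2020-02-15")))
  expect_identical(mo$end, as.Date(c("2020-02-14", "2020-03-14")))

  inst <- compute_slots(pghd_schedule("instant"), as_of = "2020-05-01")
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$start, inst$end)

  expect_error(pghd_schedule("weekly", "2020-02-01", "2020-01-01"),
               class = "pghd_error_schedule")
})

test_that("slots agree with the day-walk oracle over random periods", {
  withr::local_seed(404)
  for (rep in 1:200) {
    kind <- sample(c("weekly", "monthly"), 1)
    start <- as.Date("2019-01-01") + sample.int(700, 1)
    end <- start + sample.int(200, 1) - 1
    got <- compute_slots(pghd_schedule(kind, start, end))
    want <- oracle_slots(kind, start, end)
    expect_identical(got$start, want$start,
                     label = paste(kind, start, end, "starts"))
    expect_identical(got$end, want$end,
                     label = paste(kind, start, end, "ends"))
    # coverage: contiguous, no overlap, bounded by the period
    expect_identical(got$start[1], start)
    expect_identical(got$end[nrow(got)], end)
    if (nrow(got) > 1) {
      expect_identical(got$start[-1], got$end[-nrow(got)] + 1)
    }
    if (kind == "weekly") {
      days <- as.integer(end - start) + 1L
      expect_identical(nrow(got), as.integer(ceiling(days / 7)))
    }
  }
})

test_that("one structurally valid ServiceRequest is generated per instrument", {
  st <- mock_store()
  fx <- seed_example_repository(st)
  patient <- paste0("Patient/", fx$patients[[1]][["id"]])
  instruments <- list_instruments(st)
  expect_error(create_requests(patient, "Practitioner/d1", instruments[0, ],
                               pghd_schedule("instant")),
               class = "pghd_error_precondition")

  reqs <- create_requests(patient, "Practitioner/d1", instruments,
                          pghd_schedule("weekly", "2020-03-02", "2020-03-29"),
                          now = as.POSIXct("2020-03-02", tz = "UTC"),
                          store = st)
  expect_length(reqs, nrow(instruments))
  for (r in reqs) {
    expect_s3_class(r$resource, "fhir_resource")
    iss <- fhir_check_structure(r$resource)
    expect_identical(sum(iss$severity == "error"), 0L)
    expect_identical(r$resource$occurrenceTiming$`repeat`$periodUnit, "wk")
  }
  # each request references its own instrument
  bindings <- vapply(reqs, function(r) {
    if (r$instrument_binding$type == "questionnaire")
      r$instrument_binding$reference
    else paste0(r$instrument_binding$coding$system, "|",
                r$instrument_binding$coding$code)
  }, character(1))
  expect_identical(anyDuplicated(bindings), 0L)
})

test_that("identical active re-dispatch is refused, across requesters", {
  st <- mock_store()
  fx <- seed_example_repository(st)
  patient <- paste0("Patient/", fx$patients[[1]][["id"]])
  instruments <- list_instruments(st)[1, ]
  sched <- pghd_schedule("instant")
  create_requests(patient, "Practitioner/d1", instruments, sched,
                  now = as.POSIXct("2020-03-02", tz = "UTC"), store = st)
  # the duplicate key ignores the requester: another clinic is refused too
  expect_error(
    create_requests(patient, "Practitioner/other-clinic", instruments, sched,
                    now = as.POSIXct("2020-03-03", tz = "UTC"), store = st),
    class = "pghd_error_duplicate-request")
  # a different schedule is a different order
  ok <- create_requests(patient, "Practitioner/d1", instruments,
                        pghd_schedule("weekly", "2020-04-01", "2020-04-28"),
                        now = as.POSIXct("2020-03-03", tz = "UTC"), store = st)
  expect_length(ok, 1)
})

test_that("request status follows slot fulfilment and the clock", {
  st <- mock_store()
  fx <- seed_example_repository(st)
  patient <- paste0("Patient/", fx$patients[[1]][["id"]])
  inst <- list_instruments(st)[1, ]
  req <- create_requests(patient, "Practitioner/d1", inst,
                         pghd_schedule("weekly", "2020-01-01", "2020-01-28"),
                         now = as.POSIXct("2020-01-01", tz = "UTC"),
                         store = st)[[1]]

  expect_identical(request_status(req, now = "2019-12-25"), "upcoming")
  expect_identical(request_status(req, now = "2020-01-10"), "due")
  # report inside slot 2 (0-based index 1): 2020-01-08..14
  expect_identical(request_status(req, reports = "2020-01-09",
                                  now = "2020-01-10"), "fulfilled_current")
  expect_identical(request_status(req, reports = "2020-01-09",
                                  now = "2020-01-20"), "due")
  expect_identical(request_status(req, now = "2020-02-10"), "overdue")
  all_slots <- c("2020-01-02", "2020-01-09", "2020-01-16", "2020-01-23")
  expect_identical(request_status(req, reports = all_slots,
                                  now = "2020-02-10"), "completed")

  inst_req <- create_requests(patient, "Practitioner/d1", inst,
                              pghd_schedule("instant"),
                              now = as.POSIXct("2020-03-02", tz = "UTC"),
                              store = st)[[1]]
  expect_identical(request_status(inst_req, now = "2021-01-01"), "due")
  expect_identical(request_status(inst_req, reports = "2020-03-02",
                                  now = "2021-01-01"), "completed")
})
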