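#' @title Practitioner-side request dispatch and scheduling
#' @description
#' One FHIR ServiceRequest is generated per selected instrument (never per
#' slot); a recurring schedule travels inside the request as occurrence
#' timing. Schedules are instant, or period-bound weekly/monthly. All dates
#' are UTC calendar dates; slot boundaries are inclusive at day granularity.
#' @name requests
NULL

#' Construct a schedule
#'
#' @param kind `"instant"`, `"weekly"` or `"monthly"`.
#' @param period_start,period_end Dates bounding the recurrence (omitted for
#'   instant schedules).
#' @return A `pghd_schedule`.
#' @examples
#' pghd_schedule("weekly", "2020-01-01", "2020-01-28")
#' @export
pghd_schedule <- function(kind = c("instant", "weekly", "monthly"),
                          period_start = NULL, period_end = NULL) {
  kind <- match.arg(kind)
  if (kind == "instant") {
    if (!is.null(period_start) || !is.null(period_end)) {
      stop(pghd_error("schedule", "instant schedules carry no period"))
    }
    return(structure(list(kind = kind), class = "pghd_schedule"))
  }
  if (is.null(period_start) || is.null(period_end)) {
    stop(pghd_error("schedule", "period-bound schedules need start and end"))
  }
  period_start <- as.Date(period_start); period_end <- as.Date(period_end)
  if (period_end < period_start) {
    stop(pghd_error("schedule", "period_end precedes period_start"))
  }
  structure(list(kind = kind, period_start = period_start,
                 period_end = period_end), class = "pghd_schedule")
}

#' @export
print.pghd_schedule <- function(x, ...) {
  if (x$kind == "instant") cat("<pghd_schedule> instant\n")
  else cat("<pghd_schedule> ", x$kind, " ", format(x$period_start), " → ",
           format(x$period_end), "\n", sep = "")
  invisible(x)
}

#' Enumerate the slots of a schedule
#'
#' Instant: a single slot on the authoring date, never expiring. Weekly:
#' consecutive 7-day windows from `period_start`, the last truncated at
#' `period_end`. Monthly: calendar-month steps (clamped at short months),
#' analogously truncated. A slot counts as fulfilled when a report date
#' falls inside it; past slots stay unfillable once missed.
#'
#' @param schedule A [pghd_schedule()].
#' @param as_of Date used as the authoring date for instant schedules.
#' @param report_dates Optional vector of report dates used to mark slots
#'   fulfilled.
#' @return Tibble with columns `index` (0-based), `start`, `end`,
#'   `fulfilled`.
#' @examples
#' compute_slots(pghd_schedule("weekly", "2020-01-01", "2020-01-28"))
#' @export
compute_slots <- function(schedule, as_of = Sys.Date(), report_dates = NULL) {
  stopifnot(inherits(schedule, "pghd_schedule"))
  as_of <- as.Date(as_of)
  if (schedule$kind == "instant") {
    starts <- as_of; ends <- as_of
  } else if (schedule$kind == "weekly") {
    starts <- seq(schedule$period_start, schedule$period_end, by = "7 days")
    ends <- pmin(starts + 6, schedule$period_end)
  } else {
    starts <- schedule$period_start
    repeat {
      nxt <- lubridate::add_with_rollback(starts[length(starts)],
                                          months(1), roll_to_first = FALSE)
      if (nxt > schedule$period_end) break
      starts <- c(starts, nxt)
    }
    nxt_starts <- lubridate::add_with_rollback(starts, months(1),
                                               roll_to_first = FALSE)
    ends <- pmin(nxt_starts - 1, schedule$period_end)
  }
  fulfilled <- vapply(seq_along(starts), function(i) {
    any(as.Date(report_dates %||% as.Date(character())) >= starts[i] &
        as.Date(report_dates %||% as.Date(character())) <= ends[i])
  }, logical(1))
  tibble::tibble(index = seq_along(starts) - 1L, start = starts, end = ends,
                 fulfilled = fulfilled)
}

#' Dispatch one ServiceRequest per instrument
#'
#' Each request is created active, authored at `now`, with the schedule
#' copied into the FHIR occurrence element (an occurrenceDateTime for
#' instant, occurrenceTiming with period bounds for weekly/monthly).
#' Surveys are bound through the questionnaire-reference extension;
#' device/active-task instruments through their coding. Dispatch is guarded
#' by an idempotency key `(patient, instrument, schedule)` — requester is
#' deliberately ignored so that duplicate orders from different clinics are
#' refused and request fatigue is avoided.
#'
#' @param patient,requester Reference tokens (`"Patient/p1"`,
#'   `"Practitioner/d1"`).
#' @param instruments Instrument tibble (one row per instrument).
#' @param schedule A [pghd_schedule()].
#' @param now Authoring timestamp (UTC).
#' @param existing List of `pghd_request` objects (or a store handle via
#'   `store`) consulted for active duplicates.
#' @param store Optional [mock_store()]; active requests for the patient are
#'   searched and the new requests are POSTed there.
#' @param token Bearer token for `store`.
#' @return List of `pghd_request` objects.
#' @export
create_requests <- function(patient, requester, instruments, schedule,
                            now = Sys.time(), existing = list(), store = NULL,
                            token = if (!is.null(store)) store$token) {
  if (!is.data.frame(instruments) || nrow(instruments) == 0) {
    stop(pghd_error("precondition", "no instruments selected"))
  }
  stopifnot(inherits(schedule, "pghd_schedule"))
  if (!is.null(store)) {
    bundle <- store_interact(store, "search", "ServiceRequest",
                             params = list(patient = ref_id(patient),
                                           status = "active"),
                             token = token)
    existing <- c(existing,
                  purrr::map(bundle$entry %||% list(),
                             function(e) as_pghd_request(e$resource)))
  }
  existing_keys <- vapply(existing, function(r) {
    if (identical(r$status, "active")) request_key(r$patient, r$instrument_binding, r$schedule)
    else NA_character_
  }, character(1))
  out <- list()
  for (i in seq_len(nrow(instruments))) {
    inst <- instruments[i, ]
    binding <- instrument_binding(inst)
    key <- request_key(patient, binding, schedule)
    if (key %in% stats::na.omit(existing_keys)) {
      stop(pghd_error("duplicate-request",
                      paste0("an identical active request already exists for ",
                             patient, " / ", inst$identifier)))
    }
    existing_keys <- c(existing_keys, key)
    req <- build_request(patient, requester, inst, binding, schedule, now)
    if (!is.null(store)) {
      posted <- store_interact(store, "create", "ServiceRequest",
                               req$resource, token = token)
      req$id <- posted$id
      req$resource <- posted
    }
    out <- c(out, list(req))
  }
  out
}

instrument_binding <- function(inst) {
  if (inst$category %in% c("survey_static", "survey_adaptive")) {
    res <- inst$resource[[1]]
    ref <- if (!is.null(res) && !is.null(res[["id"]])) {
      paste0("Questionnaire/", res[["id"]])
    } else inst$identifier
    list(type = "questionnaire", reference = ref)
  } else {
    bits <- strsplit(inst$identifier, "|", fixed = TRUE)[[1]]
    list(type = "coding",
         coding = list(system = bits[1], code = bits[2],
                       display = inst$title))
  }
}

request_key <- function(patient, binding, schedule) {
  sched <- if (schedule$kind == "instant") "instant" else
    paste(schedule$kind, schedule$period_start, schedule$period_end)
  inst <- if (binding$type == "questionnaire") binding$reference else
    paste0(binding$coding$system, "|", binding$coding$code)
  paste(ref_id(patient), inst, sched, sep = "\r")
}

build_request <- function(patient, requester, inst, binding, schedule, now) {
  cfg <- pghd_config()
  now_s <- format(as.POSIXct(now, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  sr <- list(resourceType = "ServiceRequest", status = "active",
             intent = "order", subject = fhir_reference(patient),
             requester = fhir_reference(requester), authoredOn = now_s)
  if (binding$type == "questionnaire") {
    sr$extension <- list(list(url = cfg$questionnaire_extension_url,
                              valueReference = fhir_reference(binding$reference)))
  } else {
    sr$code <- list(coding = list(binding$coding))
  }
  if (schedule$kind == "instant") {
    sr$occurrenceDateTime <- format(as.Date(now_s), "%Y-%m-%d")
  } else {
    sr$occurrenceTiming <- list(
      `repeat` = list(
        boundsPeriod = list(start = format(schedule$period_start),
                            end = format(schedule$period_end)),
        frequency = 1,
        period = 1,
        periodUnit = if (schedule$kind == "weekly") "wk" else "mo"
      )
    )
  }
  structure(list(id = NULL, patient = patient, requester = requester,
                 instrument_binding = binding, schedule = schedule,
                 status = "active", authored_on = now_s,
                 resource = as_fhir_resource(sr)),
            class = "pghd_request")
}

#' Rehydrate a `pghd_request` from a ServiceRequest resource
#'
#' @param sr A ServiceRequest `fhir_resource`.
#' @return A `pghd_request`.
#' @export
as_pghd_request <- function(sr) {
  if (inherits(sr, "pghd_request")) return(sr)
  sr <- as_fhir_resource(sr)
  stopifnot(identical(sr$resourceType, "ServiceRequest"))
  cfg <- pghd_config()
  ext <- find_extension(sr$extension, cfg$questionnaire_extension_url)
  binding <- if (!is.null(ext)) {
    list(type = "questionnaire", reference = ext$valueReference$reference)
  } else if (length(sr$code$coding %||% list()) > 0) {
    co <- sr$code$coding[[1]]
    list(type = "coding", coding = list(system = co$system, code = co$code,
                                        display = co$display %||% co$code))
  } else {
    stop(pghd_error("malformed-request", "request carries no instrument binding"))
  }
  sched <- if (!is.null(sr$occurrenceTiming)) {
    rep <- sr$occurrenceTiming$`repeat`
    pghd_schedule(if (identical(rep$periodUnit, "wk")) "weekly" else "monthly",
                  rep$boundsPeriod$start, rep$boundsPeriod$end)
  } else {
    pghd_schedule("instant")
  }
  structure(list(id = sr[["id"]], patient = sr$subject$reference,
                 requester = sr$requester$reference %||% NA_character_,
                 instrument_binding = binding, schedule = sched,
                 status = sr$status, authored_on = sr$authoredOn %||% NA_character_,
                 resource = sr),
            class = "pghd_request")
}

#' @export
print.pghd_request <- function(x, ...) {
  inst <- if (x$instrument_binding$type == "questionnaire") {
    x$instrument_binding$reference
  } else {
    paste0(x$instrument_binding$coding$system, "|", x$instrument_binding$coding$code)
  }
  cat("<pghd_request> ", x$id %||% "(unposted)", " ", x$patient, " ← ",
      inst, " [", x$schedule$kind, ", ", x$status, "]\n", sep = "")
  invisible(x)
}

#' Due/overdue status of a request
#'
#' Derived solely from slot fulfilment and the clock: `completed` iff every
#' slot holds a report; otherwise `fulfilled_current` / `due` for the slot
#' containing `now`, `upcoming` before the first slot, `overdue` once `now`
#' has passed the end of an unfulfilled schedule. An instant request is due
#' immediately and never expires.
#'
#' @param request A `pghd_request`.
#' @param reports List of `pghd_report` objects (or a vector of report
#'   dates) attributed to this request.
#' @param now Evaluation date.
#' @return One of `"due"`, `"upcoming"`, `"fulfilled_current"`,
#'   `"completed"`, `"overdue"`.
#' @export
request_status <- function(request, reports = list(), now = Sys.Date()) {
  now <- as.Date(now)
  dates <- report_dates(reports, request)
  authored <- as.Date(substr(request$authored_on, 1, 10))
  slots <- compute_slots(request$schedule, as_of = authored,
                         report_dates = dates)
  if (all(slots$fulfilled)) return("completed")
  if (request$schedule$kind == "instant") return("due")
  if (now < slots$start[1]) return("upcoming")
  cur <- which(slots$start <= now & now <= slots$end)
  if (length(cur) == 0) return("overdue")   # past period_end, gaps impossible
  if (slots$fulfilled[cur[1]]) "fulfilled_current" else "due"
}

report_dates <- function(reports, request = NULL) {
  if (length(reports) == 0) return(as.Date(character()))
  if (inherits(reports, "Date") || is.character(reports)) {
    return(as.Date(reports))
  }
  dts <- purrr::map_chr(reports, function(r) {
    if (!is.null(request) && !is.null(r$request_id) && !is.null(request$id) &&
        !identical(r$request_id, request$id)) {
      stop(pghd_error("precondition",
                      "report does not reference this request"))
    }
    r$date %||% NA_character_
  })
  as.Date(dts[!is.na(dts)])
}
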