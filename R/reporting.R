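#' @title Report assembly, consent gating and submission
#' @description
#' Completed results are packaged as one transaction Bundle per request
#' fulfilment. Every entry is tagged with the patient as subject and linked
#' back to the originating ServiceRequest; the requester is recorded in the
#' resource-type-appropriate element (Observation performer, Media
#' operator, DocumentReference author, QuestionnaireResponse author).
#' Submission is gated on explicit patient consent: without it the store is
#' never contacted.
#' @name reporting
NULL

#' Assemble a tagged report from result resources
#'
#' @param resources Non-empty list of structure-valid result resources.
#' @param request The originating `pghd_request` (must have an id).
#' @param date Report date used for slot attribution.
#' @return A `pghd_report` carrying the transaction Bundle.
#' @export
assemble_report <- function(resources, request, date = Sys.Date()) {
  if (length(resources) == 0) {
    stop(pghd_error("precondition", "no resources to report"))
  }
  request <- as_pghd_request_like(request)
  patient_ref <- request$patient
  requester_ref <- request$requester
  request_ref <- paste0("ServiceRequest/", request$id %||%
                          stop(pghd_error("precondition",
                                          "request has no id; post it first")))
  tagged <- purrr::map(resources, function(r) {
    r <- as_fhir_resource(r)
    iss <- fhir_check_structure(r)
    if (!fhir_conformant(iss)) {
      stop(pghd_error("precondition",
                      paste0("resource fails structural validation: ",
                             r$resourceType)))
    }
    tag_resource(r, patient_ref, requester_ref, request_ref)
  })
  bundle <- as_fhir_resource(list(
    resourceType = "Bundle", type = "transaction",
    entry = purrr::map(tagged, function(r) {
      list(resource = unclass(r),
           request = list(method = "POST", url = r$resourceType))
    })
  ))
  structure(list(request_id = request$id, patient = patient_ref,
                 requester = requester_ref, resources = tagged,
                 bundle = bundle, submitted = FALSE, consent_given = NA,
                 date = format(as.Date(date)), assigned = character()),
            class = "pghd_report")
}

as_pghd_request_like <- function(request) {
  if (inherits(request, "pghd_request")) return(request)
  as_pghd_request(request)
}

tag_resource <- function(r, patient_ref, requester_ref, request_ref) {
  ty <- r$resourceType
  subject_ref <- fhir_reference(patient_ref)
  existing <- r$subject$reference
  if (!is.null(existing) && !identical(existing, patient_ref)) {
    stop(pghd_error("tagging",
                    paste0(ty, " already tagged with a different subject: ",
                           existing)))
  }
  r$subject <- subject_ref
  if (ty %in% c("Observation", "QuestionnaireResponse", "Media")) {
    basis <- r$basedOn %||% list()
    if (!any(vapply(basis, function(b) identical(b$reference, request_ref),
                    logical(1)))) {
      r$basedOn <- c(basis, list(fhir_reference(request_ref)))
    }
  } else if (ty == "DocumentReference") {
    rel <- r$context$related %||% list()
    r$context <- list(related = c(rel, list(fhir_reference(request_ref))))
  }
  if (!is.null(requester_ref) && !is.na(requester_ref)) {
    if (ty == "Observation") {
      r$performer <- list(fhir_reference(requester_ref))
    } else if (ty == "Media") {
      r$operator <- fhir_reference(requester_ref)
    } else if (ty == "DocumentReference") {
      r$author <- list(fhir_reference(requester_ref))
    } else if (ty == "QuestionnaireResponse") {
      r$author <- fhir_reference(requester_ref)
    }
  }
  as_fhir_resource(r)
}

#' @export
print.pghd_report <- function(x, ...) {
  cat("<pghd_report> request ", x$request_id, ", ", length(x$resources),
      " resources, ",
      if (isTRUE(x$submitted)) "submitted" else "not submitted", "\n",
      sep = "")
  invisible(x)
}

#' Submit a report, gated on patient consent
#'
#' With consent withheld the store is not contacted at all (its request log
#' gains no entry) and the report is unchanged. With consent the bundle is
#' posted as one atomic transaction; server-assigned ids are recorded on
#' the report. Re-submitting an already-submitted report is a no-op.
#'
#' @param report A `pghd_report`.
#' @param store A [mock_store()] handle.
#' @param consent Logical: did the patient confirm submission?
#' @param token Bearer token for the store.
#' @return The report, with `submitted`, `consent_given`, `outcome` and
#'   `assigned` (server locations) updated.
#' @export
submit_report <- function(report, store, consent, token = store$token) {
  stopifnot(inherits(report, "pghd_report"))
  if (isTRUE(report$submitted)) {
    report$outcome <- "already-submitted"
    return(report)
  }
  report$consent_given <- isTRUE(consent)
  if (!isTRUE(consent)) {
    report$outcome <- "declined"
    return(report)
  }
  resp <- store_interact(store, "transaction", payload = report$bundle,
                         token = token)
  report$assigned <- vapply(resp$entry, function(e) e$response$location,
                            character(1))
  report$submitted <- TRUE
  report$outcome <- "submitted"
  report
}
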