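#' @title PGHD instruments: classification, listing, resolution
#' @description
#' An *instrument* is any orderable source of patient-generated health data.
#' Four categories are supported, mirroring how a hospital FHIR repository
#' encodes them: static surveys (Questionnaire), computer-adaptive surveys
#' (Questionnaire carrying an adaptive extension whose URL points at the
#' next-question service), device-recorded measures and active tasks (both
#' ValueSet resources whose codings are bound to a category through the
#' editable coding map). Instruments are returned as one-row tibbles so
#' listings compose with dplyr verbs.
#' @name instruments
NULL

instrument_categories <- c("survey_static", "survey_adaptive",
                           "device_recorded", "active_task")

new_instrument <- function(identifier, category, title, source,
                           service_endpoint = NA_character_, result_kind,
                           resource = NULL) {
  stopifnot(category %in% instrument_categories)
  if (category == "survey_adaptive" && is.na(service_endpoint)) {
    stop(pghd_error("classification",
                    "adaptive instrument without a service endpoint"))
  }
  tibble::tibble(
    identifier = identifier, category = category, title = title,
    source = source, service_endpoint = service_endpoint,
    result_kind = result_kind, resource = list(resource)
  )
}

#' Classify one repository entry into an Instrument
#'
#' Questionnaires without the adaptive extension are static surveys; with it
#' they are adaptive surveys whose `service_endpoint` is the URL carried in
#' the extension. ValueSets are looked up coding-by-coding in the coding
#' map; the first mapped coding fixes the category (`device_recorded` or
#' `active_task`) and the result kind.
#'
#' @param entry A `fhir_resource` of type Questionnaire or ValueSet.
#' @param coding_map Coding map tibble; see [default_coding_map()].
#' @return One-row instrument tibble: `identifier`, `category`, `title`,
#'   `source`, `service_endpoint`, `result_kind`, `resource` (list-column).
#' @export
classify_instrument <- function(entry, coding_map = default_coding_map()) {
  entry <- as_fhir_resource(entry)
  cfg <- pghd_config()
  if (entry$resourceType == "Questionnaire") {
    ext <- find_extension(entry$extension, cfg$adaptive_extension_url)
    ident <- entry$url %||% paste0("Questionnaire/", entry[["id"]])
    title <- entry$title %||% entry$name %||% ident
    if (is.null(ext)) {
      return(new_instrument(ident, "survey_static", title, "repository",
                            result_kind = "QuestionnaireResponse",
                            resource = entry))
    }
    endpoint <- ext$valueUrl %||% ext$valueUri
    if (is.null(endpoint)) {
      stop(pghd_error("classification",
                      "adaptive extension carries no service URL"))
    }
    return(new_instrument(ident, "survey_adaptive", title, "external_service",
                          service_endpoint = endpoint,
                          result_kind = "QuestionnaireResponse",
                          resource = entry))
  }
  if (entry$resourceType == "ValueSet") {
    for (inc in entry$compose$include %||% list()) {
      for (con in inc$concept %||% list()) {
        hit <- lookup_coding(coding_map, inc$system %||% "", con$code %||% "")
        if (!is.null(hit) &&
            hit$category %in% c("device_recorded", "active_task")) {
          ident <- paste0(inc$system, "|", con$code)
          title <- entry$title %||% con$display %||% hit$display
          return(new_instrument(ident, hit$category, title, "repository",
                                result_kind = hit$result_types,
                                resource = entry))
        }
      }
    }
    stop(pghd_error("classification",
                    paste0("ValueSet ", entry[["id"]] %||% "?",
                           " carries no coding known to the coding map")))
  }
  stop(pghd_error("classification",
                  paste0("not an instrument resource: ", entry$resourceType)))
}

#' List the instruments hosted in a FHIR repository
#'
#' Searches the store for Questionnaire and ValueSet resources, classifies
#' each, and returns the result ordered by identifier. Entries the coding
#' map cannot classify are skipped with a warning — a shared hospital
#' repository will hold resources other applications own.
#'
#' @param store A [mock_store()] handle (the instrument repository).
#' @param coding_map Coding map tibble.
#' @param token Bearer token for the store.
#' @return Instrument tibble, zero rows for an empty repository.
#' @export
list_instruments <- function(store, coding_map = default_coding_map(),
                             token = store$token) {
  entries <- list()
  for (ty in c("Questionnaire", "ValueSet")) {
    bundle <- store_interact(store, "search", ty, token = token)
    entries <- c(entries, purrr::map(bundle$entry %||% list(), "resource"))
  }
  rows <- purrr::map(entries, function(e) {
    tryCatch(classify_instrument(e, coding_map),
             pghd_error = function(err) {
               warning(paste0("skipping unclassifiable entry ",
                              e$resourceType, "/", e$id %||% "?", ": ",
                              conditionMessage(err)), call. = FALSE)
               NULL
             })
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(new_instrument("x", "survey_static", "x", "repository",
                          result_kind = "x")[0, ])
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$identifier)
}

#' Resolve the instrument bound to a PGHD request
#'
#' A request binds its instrument either through the questionnaire-reference
#' extension (surveys; resolved against the store, at most one read) or
#' through an instrument coding in `ServiceRequest.code` (device/active
#' task; no store round-trip).
#'
#' @param request A `pghd_request` or a ServiceRequest `fhir_resource`.
#' @param store A [mock_store()] handle, consulted only for questionnaire
#'   references.
#' @param coding_map Coding map tibble.
#' @param token Bearer token for the store.
#' @return One-row instrument tibble.
#' @export
resolve_instrument <- function(request, store = NULL,
                               coding_map = default_coding_map(),
                               token = if (!is.null(store)) store$token) {
  sr <- if (inherits(request, "pghd_request")) request$resource else
    as_fhir_resource(request)
  cfg <- pghd_config()
  ext <- find_extension(sr$extension, cfg$questionnaire_extension_url)
  if (!is.null(ext)) {
    ref <- ext$valueReference$reference
    if (is.null(ref)) stop(pghd_error("malformed-request",
                                      "questionnaire extension without reference"))
    if (is.null(store)) stop(pghd_error("resolution",
                                        "questionnaire reference needs a store"))
    q <- tryCatch(store_interact(store, "read", ref, token = token),
                  `pghd_error_not-found` = function(e)
                    stop(pghd_error("resolution",
                                    paste0("dangling reference: ", ref))))
    return(classify_instrument(q, coding_map))
  }
  codings <- sr$code$coding %||% list()
  for (co in codings) {
    hit <- lookup_coding(coding_map, co$system %||% "", co$code %||% "")
    if (!is.null(hit)) {
      return(new_instrument(paste0(co$system, "|", co$code), hit$category,
                            co$display %||% hit$display, "repository",
                            service_endpoint = NA_character_,
                            result_kind = hit$result_types))
    }
  }
  if (length(codings) > 0) {
    stop(pghd_error("classification",
                    "request coding not present in the coding map"))
  }
  stop(pghd_error("malformed-request",
                  "request carries neither a questionnaire reference nor an instrument coding"))
}

find_extension <- function(extensions, url) {
  for (e in extensions %||% list()) {
    if (identical(e$url, url)) return(e)
  }
  NULL
}
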