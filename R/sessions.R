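#' @title Patient-side sessions: questionnaire administration
#' @description
#' A session interprets an instrument step by step. Static questionnaires
#' are precompiled into an ordered step sequence (groups flattened, the
#' group header kept as a display step) with `enableWhen` skip logic
#' (operators `=`, `!=`, `exists`; multiple conditions AND together).
#' Adaptive instruments start with an empty step list and a fresh session
#' UUID — the only identifier ever sent to the next-question service — and
#' grow as the service issues items. Completed sessions are finalized into
#' a FHIR QuestionnaireResponse.
#' @name sessions
NULL

supported_item_types <- c("boolean", "integer", "decimal", "string", "text",
                          "date", "choice", "display", "group")

#' Compile a static Questionnaire into ordered steps
#'
#' @param questionnaire A Questionnaire `fhir_resource`.
#' @return List of steps: `linkId`, `text`, `answer_type`, `options`,
#'   `required`, `enable_conditions`.
#' @export
compile_steps <- function(questionnaire) {
  questionnaire <- as_fhir_resource(questionnaire)
  steps <- list()
  walk_items <- function(items) {
    for (it in items %||% list()) {
      ty <- it$type %||% "(missing)"
      if (!ty %in% supported_item_types) {
        stop(pghd_error("unsupported-item",
                        paste0("item ", it$linkId %||% "?",
                               " has unsupported type '", ty, "'")))
      }
      conds <- purrr::map(it$enableWhen %||% list(), function(ew) {
        list(question = ew$question,
             operator = ew$operator,
             answer = ew_answer_value(ew))
      })
      if (ty == "group") {
        steps[[length(steps) + 1]] <<- list(
          linkId = it$linkId, text = it$text %||% "", answer_type = "display",
          options = list(), required = FALSE, enable_conditions = conds)
        walk_items(it$item)
        next
      }
      opts <- purrr::map(it$answerOption %||% list(), function(ao) {
        ao$valueCoding %||% ao$valueString %||% ao$valueInteger
      })
      if (ty == "choice" && length(opts) == 0) {
        stop(pghd_error("unsupported-item",
                        paste0("choice item ", it$linkId %||% "?",
                               " has no answer options")))
      }
      steps[[length(steps) + 1]] <<- list(
        linkId = it$linkId, text = it$text %||% "", answer_type = ty,
        options = opts, required = isTRUE(it$required),
        enable_conditions = conds)
    }
  }
  walk_items(questionnaire$item)
  ids <- vapply(steps, `[[`, "", "linkId")
  for (i in seq_along(steps)) {
    for (cnd in steps[[i]]$enable_conditions) {
      j <- match(cnd$question, ids)
      if (is.na(j) || j >= i) {
        stop(pghd_error("unsupported-item",
                        paste0("enableWhen on ", ids[i],
                               " references a linkId that does not occur earlier: ",
                               cnd$question)))
      }
    }
  }
  steps
}

ew_answer_value <- function(ew) {
  ew$answerBoolean %||% ew$answerInteger %||% ew$answerDecimal %||%
    ew$answerString %||% ew$answerDate %||% ew$answerCoding
}

#' Begin a session for one instrument under one request
#'
#' @param instrument One-row instrument tibble (see [classify_instrument()]).
#' @param request_id Identifier of the originating request.
#' @return A `pghd_session` with reference semantics: static sessions carry
#'   the precompiled steps, adaptive sessions an empty step list plus a
#'   freshly generated session UUID containing no patient-derived content.
#' @export
build_session <- function(instrument, request_id) {
  stopifnot(is.data.frame(instrument), nrow(instrument) == 1)
  env <- new.env(parent = emptyenv())
  env$answers <- list()
  env$issued <- character()
  env$status <- "in_progress"
  env$pending <- NULL
  env$transcript <- list()
  if (instrument$category %in% c("survey_static")) {
    q <- instrument$resource[[1]]
    if (is.null(q)) stop(pghd_error("precondition", "instrument carries no questionnaire"))
    iss <- fhir_check_structure(q)
    if (!fhir_conformant(iss)) {
      stop(pghd_error("precondition", "questionnaire fails structural validation"))
    }
    env$steps <- compile_steps(q)
    mode <- "static"
    uuid <- NA_character_
  } else if (instrument$category == "survey_adaptive") {
    env$steps <- list()
    mode <- "adaptive"
    uuid <- random_uuid()
  } else {
    stop(pghd_error("precondition",
                    "sessions administer survey instruments; device and active-task results enter through task_result()"))
  }
  structure(list(env = env, request_id = request_id, instrument = instrument,
                 mode = mode, session_uuid = uuid),
            class = "pghd_session")
}

# RFC-4122-shaped random identifier; draws only from the session RNG,
# never from patient fields
random_uuid <- function() {
  hx <- function(n) paste(sample(c(0:9, letters[1:6]), n, replace = TRUE),
                          collapse = "")
  paste0(hx(8), "-", hx(4), "-4", hx(3), "-",
         sample(c("8", "9", "a", "b"), 1), hx(3), "-", hx(12))
}

#' @export
print.pghd_session <- function(x, ...) {
  cat("<pghd_session> ", x$mode, " for request ", x$request_id %||% "?",
      " — ", x$env$status, ", ", length(x$env$answers), " answers\n", sep = "")
  invisible(x)
}

#' Session status
#' @param session A `pghd_session`.
#' @return `"in_progress"`, `"completed"` or `"aborted"`.
#' @export
session_status <- function(session) session$env$status

step_enabled <- function(step, answers) {
  for (cnd in step$enable_conditions) {
    got <- answers[[cnd$question]]
    ok <- switch(cnd$operator,
      exists = !is.null(got) == isTRUE(cnd$answer),
      `=` = !is.null(got) && answers_equal(got, cnd$answer),
      `!=` = !is.null(got) && !answers_equal(got, cnd$answer),
      stop(pghd_error("unsupported-item",
                      paste0("unsupported enableWhen operator: ", cnd$operator)))
    )
    if (!ok) return(FALSE)   # multiple conditions AND together
  }
  TRUE
}

answers_equal <- function(a, b) {
  if (is.list(a) || is.list(b)) {   # codings: compare system+code
    ca <- if (is.list(a)) a$code else a
    cb <- if (is.list(b)) b$code else b
    sa <- if (is.list(a)) a$system else NULL
    sb <- if (is.list(b)) b$system else NULL
    identical(ca, cb) && (is.null(sa) || is.null(sb) || identical(sa, sb))
  } else {
    isTRUE(a == b)
  }
}

answer_type_ok <- function(step, value) {
  switch(step$answer_type,
    boolean = is.logical(value) && length(value) == 1 && !is.na(value),
    integer = is.numeric(value) && length(value) == 1 &&
      abs(value - round(value)) < 1e-9,
    decimal = is.numeric(value) && length(value) == 1,
    string = ,
    text = is.character(value) && length(value) == 1,
    date = inherits(value, "Date") ||
      (is.character(value) && grepl("^\\d{4}-\\d{2}-\\d{2}$", value)),
    choice = any(vapply(step$options, answers_equal, logical(1), a = value)),
    display = is.null(value),
    FALSE
  )
}

next_enabled_index <- function(steps, answers, after) {
  i <- after + 1
  while (i <= length(steps)) {
    if (step_enabled(steps[[i]], answers)) return(i)
    i <- i + 1
  }
  NA_integer_
}

#' Advance a static session by one step
#'
#' The first call (no `answer`) issues the first enabled step. Each further
#' call records `answer` against the pending step, then issues the next
#' step whose enable conditions all hold, skipping disabled steps. Returns
#' the completion marker once none remain; the session is then `completed`.
#'
#' @param session A static `pghd_session` in progress.
#' @param answer Typed value for the pending step (`NULL` for display steps
#'   and for optional steps deliberately left unanswered).
#' @return A step (list) or a `pghd_session_complete` marker.
#' @export
next_step <- function(session, answer = NULL) {
  env <- session$env
  if (!identical(env$status, "in_progress")) {
    stop(pghd_error("protocol", "session is not in progress"))
  }
  if (session$mode != "static") {
    stop(pghd_error("protocol", "next_step() drives static sessions; use run_adaptive()"))
  }
  if (is.null(env$pending)) {
    if (!is.null(answer)) {
      stop(pghd_error("protocol", "answer supplied but no step is pending"))
    }
  } else {
    step <- env$steps[[env$pending]]
    if (!is.null(answer) || step$required) {
      if (step$answer_type == "display" && !is.null(answer)) {
        stop(pghd_error("protocol", "display steps take no answer"))
      }
      if (step$answer_type != "display") {
        if (is.null(answer)) {
          stop(pghd_error("answer-type",
                          paste0("required step ", step$linkId, " needs an answer")))
        }
        if (!answer_type_ok(step, answer)) {
          stop(pghd_error("answer-type",
                          paste0("answer for ", step$linkId,
                                 " is not a valid ", step$answer_type)))
        }
        env$answers[[step$linkId]] <- answer
      }
    }
  }
  nxt <- next_enabled_index(env$steps, env$answers, env$pending %||% 0)
  if (is.na(nxt)) {
    env$pending <- NULL
    env$status <- "completed"
    return(structure(list(), class = "pghd_session_complete"))
  }
  env$pending <- nxt
  env$issued <- c(env$issued, env$steps[[nxt]]$linkId)
  env$steps[[nxt]]
}

#' Drive a whole static session from an answer script
#'
#' @param session A static `pghd_session`.
#' @param script An answer script: tibble/data frame with columns `linkId`
#'   and `value` (list-column), or a named list `linkId -> value`. Steps are
#'   answered by linkId; display steps advance automatically.
#' @return The session, invisibly (now `completed`).
#' @export
run_session_script <- function(session, script) {
  lookup <- script_lookup(script)
  step <- next_step(session)
  while (!inherits(step, "pghd_session_complete")) {
    ans <- if (step$answer_type == "display") NULL else lookup(step$linkId)
    step <- next_step(session, ans)
  }
  invisible(session)
}

script_lookup <- function(script) {
  if (is.data.frame(script)) {
    vals <- script$value
    names(vals) <- script$linkId
    function(id) vals[[id]] %||% NULL
  } else {
    function(id) script[[id]] %||% NULL
  }
}

#' Finalize a completed static session into a QuestionnaireResponse
#'
#' One response item per answered (issued and enabled) step, linkIds
#' preserved, the source questionnaire referenced canonically, status
#' `"completed"`. The output passes structural validation and
#' [validate_response()] with zero errors.
#'
#' @param session A completed static `pghd_session`.
#' @param authored Authoring timestamp.
#' @return A QuestionnaireResponse `fhir_resource`.
#' @export
finalize_static <- function(session, authored = Sys.time()) {
  env <- session$env
  if (!identical(env$status, "completed")) {
    stop(pghd_error("not-completed", "session has not been completed"))
  }
  q <- session$instrument$resource[[1]]
  canonical <- q$url %||% paste0("Questionnaire/", q[["id"]])
  items <- list()
  for (step in env$steps) {
    if (!step$linkId %in% env$issued) next
    val <- env$answers[[step$linkId]]
    if (is.null(val)) next
    items[[length(items) + 1]] <- list(
      linkId = step$linkId, text = step$text,
      answer = list(answer_element(step$answer_type, val)))
  }
  qr <- list(resourceType = "QuestionnaireResponse",
             questionnaire = canonical, status = "completed",
             authored = format(as.POSIXct(authored, tz = "UTC"),
                               "%Y-%m-%dT%H:%M:%SZ"),
             item = items)
  as_fhir_resource(qr)
}

answer_element <- function(type, val) {
  switch(type,
    boolean = list(valueBoolean = val),
    integer = list(valueInteger = as.double(val)),
    decimal = list(valueDecimal = as.double(val)),
    string = ,
    text = list(valueString = val),
    date = list(valueDate = format(as.Date(val))),
    choice = if (is.list(val)) list(valueCoding = val) else
      if (is.character(val)) list(valueString = val) else
        list(valueInteger = as.double(val)),
    stop(pghd_error("answer-type", paste0("no FHIR answer encoding for ", type)))
  )
}

#' Extract (linkId, value) pairs from a QuestionnaireResponse
#'
#' @param qr A QuestionnaireResponse `fhir_resource`.
#' @return Tibble with `linkId` and `value` (list-column of typed values).
#' @export
extract_answers <- function(qr) {
  qr <- as_fhir_resource(qr)
  rows <- list()
  walk <- function(items) {
    for (it in items %||% list()) {
      for (an in it$answer %||% list()) {
        keys <- names(an)[startsWith(names(an), "value")]
        if (length(keys) > 0) {
          rows[[length(rows) + 1]] <<- list(linkId = it$linkId,
                                            value = an[[keys[1]]])
        }
      }
      walk(it$item)
    }
  }
  walk(qr$item)
  tibble::tibble(
    linkId = vapply(rows, `[[`, "", "linkId"),
    value = purrr::map(rows, "value")
  )
}

#' Run an adaptive session against a next-question service
#'
#' Implements the client half of the next-question exchange: repeatedly
#' POST the in-progress QuestionnaireResponse — tagged only with the random
#' session UUID, never with patient content — receive either one appended
#' item or a completed response, answer appended items from the script, and
#' stop when the service marks completion. Every exchanged payload is
#' retained verbatim on the session transcript so tests can string-scan it
#' for patient-derived content.
#'
#' @param session An adaptive `pghd_session`.
#' @param service An [adaptive_service()] handle.
#' @param script Answer script keyed by linkId; values are option scores
#'   (0-based option index) or option codings.
#' @param credentials Length-2 character vector, the static Basic-auth pair.
#' @return The final completed QuestionnaireResponse `fhir_resource`.
#' @export
run_adaptive <- function(session, service, script,
                         credentials = c("pghd", "pghd-secret")) {
  env <- session$env
  if (session$mode != "adaptive") {
    stop(pghd_error("protocol", "run_adaptive() needs an adaptive session"))
  }
  if (!identical(env$status, "in_progress")) {
    stop(pghd_error("protocol", "session is not in progress"))
  }
  lookup <- script_lookup(script)
  auth <- paste0("Basic ", jsonlite::base64_enc(paste(credentials, collapse = ":")))
  qr <- list(resourceType = "QuestionnaireResponse", status = "in-progress",
             identifier = list(system = pghd_config()$session_id_system,
                               value = session$session_uuid),
             item = list())
  repeat {
    body <- fhir_serialize(as_fhir_resource(qr))
    resp_body <- adaptive_call(service, body, auth)   # transport errors propagate
    env$transcript <- c(env$transcript, list(body), list(resp_body))
    resp <- fhir_parse(resp_body)
    if (identical(resp$status, "completed")) {
      env$status <- "completed"
      return(resp)
    }
    if (!identical(resp$status, "in-progress")) {
      stop(pghd_error("protocol", paste0("service returned status ", resp$status)))
    }
    if (length(resp$contained %||% list()) == 0) {
      stop(pghd_error("protocol",
                      "in-progress response carries no contained questionnaire"))
    }
    issued <- purrr::map(resp$contained[[1]]$item %||% list(), `[[`, "linkId")
    answered <- purrr::map_chr(resp$item %||% list(), "linkId")
    new_ids <- setdiff(unlist(issued), answered)
    if (length(new_ids) == 0) {
      stop(pghd_error("protocol",
                      "service returned neither a new item nor completion"))
    }
    qr <- unclass(resp)
    for (id in new_ids) {
      val <- lookup(id)
      if (is.null(val)) {
        stop(pghd_error("script-underrun",
                        paste0("script has no answer for issued item ", id)))
      }
      env$issued <- c(env$issued, id)
      env$answers[[id]] <- val
      item_def <- purrr::detect(resp$contained[[1]]$item,
                                function(it) identical(it$linkId, id))
      qr$item <- c(qr$item,
                   list(list(linkId = id, text = item_def$text %||% "",
                             answer = list(adaptive_answer(item_def, val)))))
    }
  }
}

# Answer an adaptive choice item: scripts give the 0-based option index or a
# coding; encode as the option's coding
adaptive_answer <- function(item_def, val) {
  if (is.list(val)) return(list(valueCoding = val))
  opts <- item_def$answerOption %||% list()
  idx <- as.integer(val) + 1L
  if (idx < 1 || idx > length(opts)) {
    stop(pghd_error("answer-type",
                    paste0("option index ", val, " out of range for ",
                           item_def$linkId)))
  }
  list(valueCoding = opts[[idx]]$valueCoding)
}

#' The adaptive session's exchange transcript
#'
#' @param session A `pghd_session`.
#' @return Character vector of the serialized request/response payloads, in
#'   exchange order.
#' @export
session_transcript <- function(session) {
  unlist(session$env$transcript) %||% character()
}
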