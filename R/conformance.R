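#' @title Semantic concordance of responses with their questionnaires
#' @description
#' Beyond structural validity, a QuestionnaireResponse must faithfully
#' reflect its source Questionnaire: only known linkIds, type-compatible
#' answers (choice answers must be one of the offered options), every
#' required-and-enabled item answered, no answers on disabled items, the
#' right questionnaire referenced, no duplicate linkIds. Enabled-ness is
#' recomputed from the response's own answers with the same evaluator the
#' session engine uses — one evaluator, two call sites — so generator and
#' validator cannot drift apart.
#' @name conformance
NULL

concordance_codes <- c("unknown-linkId", "missing-required", "type-mismatch",
                       "disabled-item-answered", "wrong-questionnaire",
                       "duplicate-linkId")

conc_issue <- function(code, linkId, detail) {
  stopifnot(code %in% concordance_codes)
  list(list(code = code, linkId = linkId, detail = detail))
}

#' Validate a QuestionnaireResponse against its Questionnaire
#'
#' @param response A QuestionnaireResponse `fhir_resource`.
#' @param questionnaire The source Questionnaire `fhir_resource`.
#' @return Tibble of concordance issues (`code`, `linkId`, `detail`),
#'   ordered by document position of the offending item; zero rows iff
#'   concordant.
#' @export
validate_response <- function(response, questionnaire) {
  response <- as_fhir_resource(response)
  questionnaire <- as_fhir_resource(questionnaire)
  if (!fhir_conformant(fhir_check_structure(response)) ||
      !fhir_conformant(fhir_check_structure(questionnaire))) {
    stop(pghd_error("precondition",
                    "structurally invalid input; run fhir_check_structure first"))
  }
  steps <- compile_steps(questionnaire)
  ids <- vapply(steps, `[[`, "", "linkId")
  issues <- list()

  canonical <- questionnaire$url %||% paste0("Questionnaire/", questionnaire[["id"]])
  refd <- response$questionnaire
  if (is.null(refd) || !(identical(refd, canonical) ||
                         identical(refd, questionnaire$url %||% "") ||
                         identical(refd, paste0("Questionnaire/",
                                                questionnaire[["id"]] %||% "")))) {
    issues <- c(issues, conc_issue("wrong-questionnaire", "",
                                   paste0("response references '",
                                          refd %||% "(none)",
                                          "', expected '", canonical, "'")))
  }

  answers_tbl <- extract_answers(response)
  dup <- unique(answers_tbl$linkId[duplicated(answers_tbl$linkId)])
  for (d in dup) {
    issues <- c(issues, conc_issue("duplicate-linkId", d,
                                   "linkId answered more than once"))
  }

  # recorded answers by linkId, for the shared enablement evaluator
  answers <- list()
  for (i in seq_len(nrow(answers_tbl))) {
    answers[[answers_tbl$linkId[i]]] <- answers_tbl$value[[i]]
  }

  for (i in seq_len(nrow(answers_tbl))) {
    id <- answers_tbl$linkId[i]
    val <- answers_tbl$value[[i]]
    j <- match(id, ids)
    if (is.na(j)) {
      issues <- c(issues, conc_issue("unknown-linkId", id,
                                     "linkId not present in the questionnaire"))
      next
    }
    step <- steps[[j]]
    if (!step_enabled(step, answers)) {
      issues <- c(issues, conc_issue("disabled-item-answered", id,
                                     "item is disabled by its enableWhen conditions"))
      next
    }
    if (!answer_type_ok(step, val)) {
      issues <- c(issues, conc_issue("type-mismatch", id,
                                     paste0("answer is not a valid ",
                                            step$answer_type,
                                            if (step$answer_type == "choice")
                                              " (or not an offered option)" else "")))
    }
  }

  for (j in seq_along(steps)) {
    step <- steps[[j]]
    if (step$answer_type %in% c("display", "group")) next
    if (step$required && step_enabled(step, answers) &&
        is.null(answers[[step$linkId]])) {
      issues <- c(issues, conc_issue("missing-required", step$linkId,
                                     "required enabled item left unanswered"))
    }
  }

  out <- tibble::tibble(
    code = vapply(issues, `[[`, "", "code"),
    linkId = vapply(issues, `[[`, "", "linkId"),
    detail = vapply(issues, `[[`, "", "detail")
  )
  pos <- match(out$linkId, ids)
  out[order(ifelse(is.na(pos), 0L, pos)), , drop = FALSE]
}

#' Report-level tagging checks
#'
#' Every bundle entry must carry the report's patient as subject and link
#' back to the originating request.
#'
#' @param report A `pghd_report` from [assemble_report()].
#' @return Tibble of issues (`code`, `linkId` here the entry's resource
#'   type and index, `detail`); zero rows iff conformant.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "pghd_report"))
  request_ref <- paste0("ServiceRequest/", report$request_id)
  issues <- list()
  entries <- report$bundle$entry %||% list()
  rep_issue <- function(code, where, detail) {
    list(list(code = code, linkId = where, detail = detail))
  }
  for (i in seq_along(entries)) {
    r <- entries[[i]]$resource
    tag <- paste0(r$resourceType, "[", i, "]")
    subj <- r$subject$reference
    if (is.null(subj) || !identical(subj, report$patient)) {
      issues <- c(issues, rep_issue("wrong-subject", tag,
                                    paste0("entry subject '", subj %||% "(none)",
                                           "' differs from report patient")))
    }
    basis <- if (identical(r$resourceType, "DocumentReference")) {
      purrr::map_chr(r$context$related %||% list(),
                     function(x) x$reference %||% "")
    } else {
      purrr::map_chr(r$basedOn %||% list(), function(x) x$reference %||% "")
    }
    if (!request_ref %in% basis) {
      issues <- c(issues, rep_issue("missing-request-basis", tag,
                                    "entry does not reference the originating request"))
    }
  }
  tibble::tibble(
    code = vapply(issues, `[[`, "", "code"),
    linkId = vapply(issues, `[[`, "", "linkId"),
    detail = vapply(issues, `[[`, "", "detail")
  )
}
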