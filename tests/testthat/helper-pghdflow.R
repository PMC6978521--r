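# Shared fixtures and independent oracles. Oracles deliberately re-derive
# results by brute force so they share no code path with the implementation.

# -- tiny questionnaires ------------------------------------------------------

tiny_questionnaire <- function(items, id = "q-tiny",
                               url = paste0("urn:test:", id)) {
  as_fhir_resource(list(resourceType = "Questionnaire", id = id, url = url,
                        status = "active", item = items))
}

q_item <- function(linkId, type = "boolean", text = linkId, required = FALSE,
                   enableWhen = NULL, answerOption = NULL, item = NULL) {
  it <- list(linkId = linkId, text = text, type = type)
  if (required) it$required <- TRUE
  if (!is.null(enableWhen)) it$enableWhen <- enableWhen
  if (!is.null(answerOption)) it$answerOption <- answerOption
  if (!is.null(item)) it$item <- item
  it
}

ew <- function(question, operator = "=", answerBoolean = TRUE) {
  list(list(question = question, operator = operator,
            answerBoolean = answerBoolean))
}

static_instrument <- function(q) classify_instrument(q)

# -- day-walk slot oracle -----------------------------------------------------
# Walks the period one day at a time, opening a new window every 7 days
# (weekly) or at each calendar-month anniversary (monthly). Independent of
# compute_slots().

oracle_slots <- function(kind, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  days <- seq(start, end, by = "1 day")
  if (kind == "weekly") {
    idx <- as.integer(days - start) %/% 7L
  } else {
    anniversaries <- start
    repeat {
      nxt <- lubridate::add_with_rollback(
        anniversaries[length(anniversaries)], months(1),
        roll_to_first = FALSE)
      if (nxt > end) break
      anniversaries <- c(anniversaries, nxt)
    }
    idx <- vapply(days, function(d) sum(anniversaries <= d) - 1L, integer(1))
  }
  agg <- split(days, idx)
  tibble::tibble(index = as.integer(names(agg)),
                 start = as.Date(unname(vapply(agg, function(d) format(min(d)), ""))),
                 end = as.Date(unname(vapply(agg, function(d) format(max(d)), ""))))
}

# -- skip-logic truth-table oracle -------------------------------------------
# Re-evaluates enableWhen tables directly from the questionnaire JSON over a
# named list of boolean answers; AND semantics, '='/'!='/'exists'.

oracle_enabled_set <- function(questionnaire, answers) {
  enabled <- character()
  for (it in questionnaire$item) {
    ok <- TRUE
    for (cond in it$enableWhen %||% list()) {
      got <- answers[[cond$question]]
      # a disabled source never got answered
      if (!cond$question %in% enabled) got <- NULL
      ok <- ok && switch(cond$operator,
        "=" = !is.null(got) && identical(got, cond$answerBoolean),
        "!=" = !is.null(got) && !identical(got, cond$answerBoolean),
        "exists" = identical(!is.null(got), cond$answerBoolean))
      if (!ok) break
    }
    if (ok) enabled <- c(enabled, it$linkId)
  }
  enabled
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- graded-response numerical oracle ----------------------------------------
# Category probabilities recomputed from first principles and differentiated
# numerically; no analytic-information code shared with the package.

oracle_cat_probs <- function(a, b, theta) {
  pstar <- c(1, stats::plogis(a * (theta - b)), 0)
  pstar[-length(pstar)] - pstar[-1]
}

oracle_item_info <- function(a, b, theta, h = 1e-5) {
  p0 <- oracle_cat_probs(a, b, theta)
  dp <- (oracle_cat_probs(a, b, theta + h) -
           oracle_cat_probs(a, b, theta - h)) / (2 * h)
  sum(dp^2 / pmax(p0, 1e-12))
}

oracle_posterior <- function(administered, bank,
                             grid = seq(-6, 6, length.out = 2001)) {
  w <- stats::dnorm(grid)
  for (i in seq_len(nrow(administered))) {
    j <- match(administered$linkId[i], bank$linkId)
    w <- w * vapply(grid, function(th) {
      oracle_cat_probs(bank$discrimination[j], bank$thresholds[[j]],
                       th)[administered$score[i] + 1]
    }, numeric(1))
  }
  mean_ <- sum(grid * w) / sum(w)
  list(theta = mean_, se = sqrt(sum((grid - mean_)^2 * w) / sum(w)))
}

# -- seeded-violation corpus --------------------------------------------------
# 20 resources; expectations transcribed by hand from the published R4
# structure definitions (the same source the official validator implements):
# each entry records the exact (code, path) pairs expected at error severity.

violation_corpus <- function() {
  obs_code <- list(coding = list(list(system = "http://loinc.org",
                                      code = "55423-8")))
  mk <- function(tree, expect) list(tree = tree, expect = expect)
  err <- function(code, path) list(code = code, path = path)
  list(
    mk(list(resourceType = "Questionnaire", id = "v01"),
       list(err("cardinality-min", "Questionnaire.status"))),
    mk(list(resourceType = "Observation", status = "final", code = obs_code,
            valueQuantity = list(value = 1, unit = "steps"),
            valueBoolean = TRUE),
       list(err("wrong-type", "Observation.value[x]"))),
    mk(list(resourceType = "Observation", status = "final"),
       list(err("cardinality-min", "Observation.code"))),
    mk(list(resourceType = "QuestionnaireResponse", questionnaire = "urn:q"),
       list(err("cardinality-min", "QuestionnaireResponse.status"))),
    mk(list(resourceType = "Patient", id = "v05",
            name = list(family = "Solo")),   # object where array required
       list(err("wrong-type", "Patient.name"))),
    mk(list(resourceType = "ServiceRequest", status = "active",
            subject = list(reference = "Patient/p")),
       list(err("cardinality-min", "ServiceRequest.intent"))),
    mk(list(resourceType = "ServiceRequest", status = "active",
            intent = "order"),
       list(err("cardinality-min", "ServiceRequest.subject"))),
    mk(list(resourceType = "Bundle", type = "transaction",
            entry = list(list(request = list(url = "Observation")))),
       list(err("cardinality-min", "Bundle.entry[1].request.method"))),
    mk(list(resourceType = "OperationOutcome",
            issue = list(list(code = "invalid"))),
       list(err("cardinality-min", "OperationOutcome.issue[1].severity"))),
    mk(list(resourceType = "Media", status = "completed"),
       list(err("cardinality-min", "Media.content"))),
    mk(list(resourceType = "DocumentReference", status = "current"),
       list(err("cardinality-min", "DocumentReference.content"))),
    mk(list(resourceType = "ValueSet", status = "active",
            compose = list(inactive = FALSE)),
       list(err("cardinality-min", "ValueSet.compose.include"))),
    mk(list(resourceType = "Observation", status = "final", code = obs_code,
            valueBoolean = "true"),
       list(err("wrong-type", "Observation.valueBoolean"))),
    mk(list(resourceType = "Observation", status = "final", code = obs_code,
            valueInteger = 3.5),
       list(err("wrong-type", "Observation.valueInteger"))),
    mk(list(resourceType = "Questionnaire", status = "active",
            item = list(list(type = "boolean", text = "no linkId"))),
       list(err("cardinality-min", "Questionnaire.item[1].linkId"))),
    mk(list(resourceType = "Questionnaire", status = "active",
            item = list(list(linkId = "a", type = "boolean",
                             enableWhen = list(list(question = "z",
                                                    operator = "="))))),
       list(err("cardinality-min",
                "Questionnaire.item[1].enableWhen[1].answer[x]"))),
    mk(list(resourceType = "Patient", id = "v17", favouriteColour = "teal"),
       list()),   # unknown element: warning only, no errors
    mk(list(resourceType = "Observation", status = "final", code = obs_code,
            valueQuantity = list(value = 4200, unit = "steps")),
       list()),
    mk(list(resourceType = "Patient", id = "v19",
            name = list(list(family = "Ok", given = list("A")))),
       list()),
    mk(list(resourceType = "ServiceRequest", status = "active",
            intent = "order", subject = list(reference = "Patient/p"),
            authoredOn = "2020-01-01T00:00:00Z"),
       list())
  )
}

strip_server_id <- function(tree) {
  tree[["id"]] <- NULL
  tree
}

# seed a store with a canonical small repository:
# 2 static questionnaires, 1 adaptive, 1 device ValueSet
seed_example_repository <- function(store, seed = 5L) {
  fx <- generate_fixtures(fixture_spec(seed = seed, n_static_q = 2,
                                       n_adaptive_q = 1,
                                       n_device_valuesets = 1))
  store_seed(store, fx$all)
  fx
}

new_instrument_for_test <- function(q) {
  tibble::tibble(identifier = q$url %||% q[["id"]], category = "survey_static",
                 title = "t", source = "repository",
                 service_endpoint = NA_character_,
                 result_kind = "QuestionnaireResponse", resource = list(q))
}

adaptive_script_for_test <- function(bank, value = 0) {
  tibble::tibble(linkId = bank$linkId,
                 value = rep(list(as.double(value)), nrow(bank)))
}

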