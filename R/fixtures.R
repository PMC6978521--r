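#' @title Deterministic synthetic fixture generation
#' @description
#' Generates the whole test world: patients with high-entropy synthetic
#' names and identifiers (so privacy string-scans of adaptive payloads are
#' meaningful), static questionnaires with mixed item types and
#' configurable skip-logic density, adaptive questionnaire stubs carrying
#' the service endpoint, and device/active-task ValueSets drawn from the
#' coding map. Identical seeds give byte-identical corpora.
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param seed Integer RNG seed; identical specs generate byte-identical
#'   NDJSON corpora.
#' @param n_patients,n_static_q,n_adaptive_q,n_device_valuesets Resource
#'   counts.
#' @param items_per_q Length-2 integer range of items per questionnaire.
#' @param skip_logic_density Probability that a non-first item carries an
#'   enableWhen condition on an earlier boolean item.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_patients = 3L, n_static_q = 2L,
                         n_adaptive_q = 1L, n_device_valuesets = 2L,
                         items_per_q = c(4L, 8L), skip_logic_density = 0.3) {
  stopifnot(seed == as.integer(seed), skip_logic_density >= 0,
            skip_logic_density <= 1, length(items_per_q) == 2)
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 n_static_q = n_static_q, n_adaptive_q = n_adaptive_q,
                 n_device_valuesets = n_device_valuesets,
                 items_per_q = items_per_q,
                 skip_logic_density = skip_logic_density),
            class = "fixture_spec")
}

# high-entropy token: long enough that accidental substring hits in JSON
# payloads are implausible
rand_token <- function(n = 16) {
  paste(sample(c(letters, LETTERS, 0:9), n, replace = TRUE), collapse = "")
}

#' Generate the synthetic fixture corpus
#'
#' @param spec A [fixture_spec()].
#' @param adaptive_endpoint Service URL written into adaptive stubs.
#' @return Named list: `patients`, `practitioners`, `questionnaires`
#'   (static), `adaptive` (stubs), `valuesets` — all `fhir_resource` trees
#'   passing [fhir_check_structure()] — plus `all` (the flat corpus in a
#'   fixed order).
#' @export
generate_fixtures <- function(spec = fixture_spec(),
                              adaptive_endpoint = "http://cat.example/next-q") {
  stopifnot(inherits(spec, "fixture_spec"))
  cfg <- pghd_config()
  map <- default_coding_map()
  withr::with_seed(spec$seed, {
    patients <- purrr::map(seq_len(spec$n_patients), function(i) {
      list(resourceType = "Patient", id = paste0("pat-", rand_token(10)),
           identifier = list(list(system = "urn:pghdflow:mrn",
                                  value = rand_token(12))),
           name = list(list(family = paste0("Z", rand_token(11)),
                            given = list(paste0("Q", rand_token(11))))),
           gender = sample(c("male", "female", "other"), 1),
           birthDate = format(as.Date("1950-01-01") +
                                sample.int(20000, 1), "%Y-%m-%d"))
    })
    practitioners <- purrr::map(seq_len(max(1, spec$n_patients %/% 3)),
                                function(i) {
      list(resourceType = "Practitioner",
           id = paste0("prac-", rand_token(10)),
           name = list(list(family = paste0("Y", rand_token(11)))))
    })
    questionnaires <- purrr::map(seq_len(spec$n_static_q), function(i) {
      synth_questionnaire(sprintf("static-q-%02d", i), spec)
    })
    adaptive <- purrr::map(seq_len(spec$n_adaptive_q), function(i) {
      list(resourceType = "Questionnaire", id = sprintf("adaptive-q-%02d", i),
           title = sprintf("Synthetic adaptive instrument %d", i),
           status = "active",
           extension = list(list(url = cfg$adaptive_extension_url,
                                 valueUrl = adaptive_endpoint)))
    })
    device_rows <- map[map$category %in% c("device_recorded", "active_task") &
                         map$kind != "health_record", , drop = FALSE]
    picks <- device_rows[seq_len(min(spec$n_device_valuesets,
                                     nrow(device_rows))), , drop = FALSE]
    valuesets <- purrr::map(seq_len(nrow(picks)), function(i) {
      row <- picks[i, ]
      list(resourceType = "ValueSet", id = paste0("vs-", row$kind),
           title = row$display, status = "active",
           compose = list(include = list(list(
             system = row$system,
             concept = list(list(code = row$code, display = row$display))))))
    })
  })
  out <- list(patients = purrr::map(patients, as_fhir_resource),
              practitioners = purrr::map(practitioners, as_fhir_resource),
              questionnaires = purrr::map(questionnaires, as_fhir_resource),
              adaptive = purrr::map(adaptive, as_fhir_resource),
              valuesets = purrr::map(valuesets, as_fhir_resource))
  out$all <- c(out$patients, out$practitioners, out$questionnaires,
               out$adaptive, out$valuesets)
  out
}

# a static questionnaire with mixed item types; skip logic conditions on an
# earlier boolean item at the configured density
synth_questionnaire <- function(id, spec) {
  n <- sample(seq(spec$items_per_q[1], spec$items_per_q[2]), 1)
  types <- c("boolean", "integer", "decimal", "string", "date", "choice")
  items <- list()
  bool_ids <- character()
  for (i in seq_len(n)) {
    ty <- if (i == 1) "boolean" else sample(types, 1)
    link <- sprintf("%s-item-%02d", id, i)
    it <- list(linkId = link, text = sprintf("Synthetic question %d", i),
               type = ty, required = stats::runif(1) < 0.6)
    if (ty == "choice") {
      it$answerOption <- purrr::map(1:3, function(k) {
        list(valueCoding = list(system = "urn:pghdflow:answers",
                                code = sprintf("%s-opt-%d", link, k),
                                display = sprintf("Choice %d", k)))
      })
    }
    if (length(bool_ids) > 0 && stats::runif(1) < spec$skip_logic_density) {
      src <- sample(bool_ids, 1)
      it$enableWhen <- list(list(question = src, operator = "=",
                                 answerBoolean = sample(c(TRUE, FALSE), 1)))
    }
    if (ty == "boolean") bool_ids <- c(bool_ids, link)
    items[[i]] <- it
  }
  list(resourceType = "Questionnaire", id = id,
       url = paste0("urn:pghdflow:questionnaire:", id),
       title = paste0("Synthetic static survey ", id), status = "active",
       item = items)
}

#' Write a fixture corpus as NDJSON
#'
#' @param fixtures Output of [generate_fixtures()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fixture_corpus <- function(fixtures, path) {
  fhir_write_ndjson(fixtures$all, path)
}

#' Deterministic answer script for a static questionnaire
#'
#' Generates type-appropriate answers for every item (enabled or not — the
#' session engine only consumes answers for issued steps).
#'
#' @param questionnaire A Questionnaire `fhir_resource`.
#' @param seed RNG seed.
#' @return Script tibble with `linkId` and `value` list-column.
#' @export
synth_answer_script <- function(questionnaire, seed = 1L) {
  steps <- compile_steps(questionnaire)
  steps <- purrr::keep(steps, function(s) !s$answer_type %in% c("display", "group"))
  withr::with_seed(seed, {
    vals <- purrr::map(steps, function(s) {
      switch(s$answer_type,
        boolean = sample(c(TRUE, FALSE), 1),
        integer = as.double(sample.int(10, 1)),
        decimal = round(stats::runif(1, 0, 100), 2),
        string = ,
        text = paste0("ans-", rand_token(6)),
        date = format(as.Date("2020-01-01") + sample.int(365, 1), "%Y-%m-%d"),
        choice = s$options[[sample.int(length(s$options), 1)]]
      )
    })
  })
  tibble::tibble(linkId = vapply(steps, `[[`, "", "linkId"), value = vals)
}
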