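#' Run the full request-to-report lifecycle against a mock store
#'
#' Seeds the store with a deterministic fixture corpus, dispatches one
#' ServiceRequest per instrument for the first patient, administers a
#' static survey session from a scripted answer set, runs an adaptive
#' session against the bundled reference service, encodes a device
#' blood-pressure import plus an active-task result, assembles tagged
#' report bundles and submits them with consent. The same seed against two
#' independently configured stores yields element-tree-identical persisted
#' resources modulo server-assigned ids.
#'
#' @param store A [mock_store()] handle; a fresh one is created by default.
#' @param seed Integer seed driving fixtures, scripts and the item bank.
#' @param consent Whether the patient consents to submission.
#' @return Named list: `store`, `requests`, `reports`, `summary` (tibble
#'   with one row per submitted resource: `request`, `resourceType`,
#'   `location`, `status`).
#' @export
pghd_demo_e2e <- function(store = mock_store(), seed = 1L, consent = TRUE) {
  fixtures <- generate_fixtures(fixture_spec(seed = seed))
  store_seed(store, fixtures$all)
  patient <- paste0("Patient/", fixtures$patients[[1]]$id)
  requester <- paste0("Practitioner/", fixtures$practitioners[[1]]$id)

  instruments <- list_instruments(store)
  schedule <- pghd_schedule("instant")
  now <- as.POSIXct("2020-03-02 09:00:00", tz = "UTC")
  requests <- create_requests(patient, requester, instruments, schedule,
                              now = now, store = store)
  names(requests) <- instruments$identifier

  bank <- synthetic_item_bank(n_items = 6, seed = seed)
  service <- adaptive_service(bank, se_threshold = 0.3)
  adapter <- synthetic_bp_export(n = 5, start = as.Date("2020-02-24"),
                                 seed = seed)
  reports <- list()
  for (i in seq_len(nrow(instruments))) {
    inst <- instruments[i, ]
    req <- requests[[i]]
    resources <- switch(inst$category,
      survey_static = {
        sess <- build_session(inst, req$id)
        script <- synth_answer_script(inst$resource[[1]], seed = seed)
        run_session_script(sess, script)
        list(finalize_static(sess, authored = now))
      },
      survey_adaptive = {
        sess <- withr::with_seed(seed + i, build_session(inst, req$id))
        script <- adaptive_script_for(bank, seed = seed)
        list(run_adaptive(sess, service, script))
      },
      device_recorded = {
        results <- fetch_external_vitals(adapter, "device-token",
                                         window = as.Date(c("2020-02-24",
                                                            "2020-03-01")))
        if (identical(inst$result_kind, "Observation") &&
            grepl("55423-8", inst$identifier)) {
          results <- list(task_result("step_count",
                                      withr::with_seed(seed, sample(2000:12000, 1)),
                                      effective_time = now))
        }
        purrr::flatten(purrr::map(results, encode_result))
      },
      active_task = {
        kind <- default_coding_map()$kind[match(inst$identifier,
                    paste0(default_coding_map()$system, "|",
                           default_coding_map()$code))]
        purrr::flatten(purrr::map(list(synth_task_result(kind, seed, now)),
                                  encode_result))
      }
    )
    rep <- assemble_report(resources, req, date = as.Date(now))
    rep <- submit_report(rep, store, consent = consent)
    reports[[inst$identifier]] <- rep
  }
  summary <- purrr::imap_dfr(reports, function(rep, ident) {
    if (length(rep$assigned) == 0) {
      return(tibble::tibble(request = rep$request_id,
                            resourceType = purrr::map_chr(rep$resources,
                                                          "resourceType"),
                            location = NA_character_, status = rep$outcome))
    }
    tibble::tibble(request = rep$request_id,
                   resourceType = purrr::map_chr(rep$resources, "resourceType"),
                   location = rep$assigned, status = rep$outcome)
  })
  list(store = store, requests = requests, reports = reports,
       summary = summary)
}

# deterministic synthetic payload for an active-task kind
synth_task_result <- function(kind, seed, now) {
  withr::with_seed(seed, switch(kind,
    range_of_motion = task_result(kind, round(stats::runif(1, 40, 160), 1),
                                  effective_time = now),
    tapping_speed = task_result(kind, round(stats::runif(1, 2, 7), 2),
                                effective_time = now),
    peg_hole = task_result(kind, round(stats::runif(1, 15, 60), 1),
                           effective_time = now),
    paced_addition = task_result(kind, sample(10:60, 1), effective_time = now),
    tower_of_hanoi = task_result(kind, sample(c(TRUE, FALSE), 1),
                                 effective_time = now),
    stroop = task_result(kind, round(stats::runif(1, 0.4, 2.5), 3),
                         effective_time = now),
    spatial_span = task_result(kind, sample(3:9, 1), effective_time = now),
    amsler_grid = task_result(kind, list(finding = sample(c(TRUE, FALSE), 1),
                                         image = jsonlite::base64_enc(
                                           charToRaw("synthetic-png-bytes"))),
                              effective_time = now),
    stop(pghd_error("encoding", paste0("no synthetic generator for ", kind)))
  ))
}

# script answering every bank item with a deterministic option index
adaptive_script_for <- function(bank, seed = 1L) {
  withr::with_seed(seed, {
    vals <- purrr::map(seq_len(nrow(bank)), function(i) {
      n_opt <- length(bank$options[[i]])
      as.double(sample.int(n_opt, 1) - 1L)
    })
  })
  tibble::tibble(linkId = bank$linkId, value = vals)
}
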