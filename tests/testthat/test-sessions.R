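test_that("groups flatten into display-headed step sequences", {
  q <- tiny_questionnaire(list(
    q_item("a", "boolean"),
    q_item("grp", "group", text = "About sleep", item = list(
      q_item("b", "integer"), q_item("c", "string"))),
    q_item("d", "date"),
    q_item("e", "decimal")
  ))
  steps <- compile_steps(q)   # 5 questions + group header = 6 steps
  expect_length(steps, 6)
  expect_identical(vapply(steps, `[[`, "", "linkId"),
                   c("a", "grp", "b", "c", "d", "e"))
  expect_identical(steps[[2]]$answer_type, "display")

  bad <- tiny_questionnaire(list(list(linkId = "x", type = "attachment")),
                            id = "q-bad")
  inst <- new_instrument_for_test(bad)
  expect_error(build_session(inst, "r1"),
               class = "pghd_error_unsupported-item")
})

test_that("skip logic issues steps per the enable conditions", {
  q <- tiny_questionnaire(list(
    q_item("a", "boolean", required = TRUE),
    q_item("b", "integer", enableWhen = ew("a", "=", TRUE)),
    q_item("c", "boolean")
  ))
  s <- build_session(static_instrument(q), "r1")
  st1 <- next_step(s)
  expect_identical(st1$linkId, "a")
  st2 <- next_step(s, FALSE)          # a = FALSE disables b
  expect_identical(st2$linkId, "c")
  done <- next_step(s, TRUE)
  expect_s3_class(done, "pghd_session_complete")
  expect_identical(session_status(s), "completed")
  qr <- finalize_static(s)
  expect_false("b" %in% extract_answers(qr)$linkId)

  # without conditions, steps come in document order
  s2 <- build_session(static_instrument(q), "r2")
  expect_identical(next_step(s2)$linkId, "a")
  expect_identical(next_step(s2, TRUE)$linkId, "b")
  expect_identical(next_step(s2, 4)$linkId, "c")
})

test_that("type errors leave the session state unchanged", {
  q <- tiny_questionnaire(list(q_item("a", "integer", required = TRUE)))
  s <- build_session(static_instrument(q), "r1")
  expect_error(next_step(s, TRUE), class = "pghd_error_protocol") # none pending
  next_step(s)
  expect_error(next_step(s, "seven"), class = "pghd_error_answer-type")
  expect_identical(session_status(s), "in_progress")
  expect_error(finalize_static(s), class = "pghd_error_not-completed")
  next_step(s, 7)
  expect_identical(session_status(s), "completed")
  ans <- extract_answers(finalize_static(s))
  expect_identical(ans$linkId, "a")
  expect_identical(ans$value[[1]], 7)
})

test_that("scripted sessions reproduce their scripts exactly", {
  # answer fidelity across generated questionnaires and scripts
  for (seed in 1:25) {
    fx <- generate_fixtures(fixture_spec(seed = seed, n_static_q = 1,
                                         skip_logic_density = 0.5))
    q <- fx$questionnaires[[1]]
    script <- synth_answer_script(q, seed = seed)
    s <- build_session(static_instrument(q), "r1")
    run_session_script(s, script)
    qr <- finalize_static(s)
    expect_length(fhir_check_structure(qr)$severity, 0)
    expect_identical(nrow(validate_response(qr, q)), 0L)
    got <- extract_answers(qr)
    want <- script[script$linkId %in% got$linkId, ]
    expect_identical(got$linkId, want$linkId)
    for (i in seq_len(nrow(got))) {
      g <- got$value[[i]]; w <- want$value[[i]]
      if (is.list(w)) {
        expect_identical(g$code, w$code)
      } else {
        expect_identical(g, w)
      }
    }
  }
})

test_that("issued steps equal the brute-force condition-table evaluation", {
  # questionnaires with <= 4 boolean items and random enableWhen tables
  withr::local_seed(77)
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    items <- list(q_item("i1", "boolean"))
    for (i in 2:n) {
      cond <- NULL
      if (stats::runif(1) < 0.7) {
        cond <- list(list(question = paste0("i", sample(i - 1, 1)),
                          operator = sample(c("=", "!=", "exists"), 1),
                          answerBoolean = sample(c(TRUE, FALSE), 1)))
      }
      items[[i]] <- q_item(paste0("i", i), "boolean", enableWhen = cond)
    }
    q <- tiny_questionnaire(items, id = paste0("q-bf-", rep))
    answers <- stats::setNames(as.list(sample(c(TRUE, FALSE), n, TRUE)),
                               paste0("i", seq_len(n)))
    s <- build_session(static_instrument(q), "r")
    run_session_script(s, answers)
    expect_identical(unique(s$env$issued), oracle_enabled_set(q, answers),
                     label = paste("case", rep))
  }
})

test_that("adaptive sessions exhaust a small bank when SE cannot stop them", {
  bank <- synthetic_item_bank(n_items = 3, seed = 11)
  srv <- adaptive_service(bank, se_threshold = 0)   # unattainable precision
  fx <- generate_fixtures(fixture_spec(seed = 4))
  inst <- classify_instrument(fx$adaptive[[1]])
  withr::local_seed(1)
  s <- build_session(inst, "r-adpt")
  expect_identical(length(s$env$issued), 0L)
  expect_match(s$session_uuid,
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
  qr <- run_adaptive(s, srv, adaptive_script_for_test(bank))
  expect_identical(qr$status, "completed")
  expect_identical(length(s$env$issued), 3L)                 # bank exhausted
  expect_length(qr$item, 3)
  score_ext <- Filter(function(e) identical(e$url,
                                            pghd_config()$score_extension_url),
                      qr$extension)
  expect_length(score_ext, 1)
})

test_that("adaptive exchanges carry no patient-derived content", {
  fx <- generate_fixtures(fixture_spec(seed = 8))
  patient <- fx$patients[[1]]
  bank <- synthetic_item_bank(n_items = 4, seed = 2)
  srv <- adaptive_service(bank)
  inst <- classify_instrument(fx$adaptive[[1]])
  withr::local_seed(9)
  s <- build_session(inst, "r-priv")
  run_adaptive(s, srv, adaptive_script_for_test(bank, 1))
  payloads <- session_transcript(s)
  expect_gt(length(payloads), 1)
  fields <- c(patient[["id"]], patient$identifier[[1]]$value,
              patient$name[[1]]$family, patient$name[[1]]$given[[1]])
  for (f in fields) {
    expect_false(any(grepl(f, payloads, fixed = TRUE)),
                 label = paste("patient field leaked:", f))
  }
  expect_true(any(grepl(s$session_uuid, payloads, fixed = TRUE)))
})

test_that("an unreachable service leaves the session resumable", {
  bank <- synthetic_item_bank(n_items = 3, seed = 11)
  srv <- adaptive_service(bank, se_threshold = 0)
  fx <- generate_fixtures(fixture_spec(seed = 4))
  inst <- classify_instrument(fx$adaptive[[1]])
  withr::local_seed(2)
  s <- build_session(inst, "r-int")
  service_set_online(srv, FALSE)
  expect_error(run_adaptive(s, srv, adaptive_script_for_test(bank)),
               class = "pghd_error_transport")
  expect_identical(session_status(s), "in_progress")
  service_set_online(srv, TRUE)
  qr <- run_adaptive(s, srv, adaptive_script_for_test(bank))
  expect_identical(qr$status, "completed")
})

test_that("session tidiers summarize answers and progress", {
  q <- tiny_questionnaire(list(q_item("a", "boolean", required = TRUE),
                               q_item("b", "integer", required = TRUE)))
  s <- build_session(static_instrument(q), "r1")
  run_session_script(s, list(a = TRUE, b = 3))
  td <- tidy(s)
  expect_identical(sort(td$linkId), c("a", "b"))
  gl <- glance(s)
  expect_identical(gl$status, "completed")
  expect_identical(gl$n_answered, 2L)
})
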