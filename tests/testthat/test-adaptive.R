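test_that("EAP scoring matches its stated prior and a dense-grid oracle", {
  bank <- synthetic_item_bank(n_items = 6, seed = 5)
  none <- tibble::tibble(linkId = character(), score = integer())
  expect_identical(eap_estimate(none, bank), list(theta = 0, se = 1))

  # all answers at the lowest option drive the estimate strictly below 0,
  # and the estimate tracks an independent dense-grid posterior
  low <- tibble::tibble(linkId = bank$linkId, score = 0L)
  est <- eap_estimate(low, bank)
  orc <- oracle_posterior(low, bank)
  expect_lt(est$theta, 0)
  expect_lt(orc$theta, 0)
  expect_equal(est$theta, orc$theta, tolerance = 0.02)
  expect_equal(est$se, orc$se, tolerance = 0.02)

  high <- tibble::tibble(linkId = bank$linkId,
                         score = vapply(bank$thresholds, length, 0L))
  expect_gt(eap_estimate(high, bank)$theta, 0)

  # deterministic: identical state, identical estimate
  expect_identical(eap_estimate(low, bank), eap_estimate(low, bank))
})

test_that("item selection equals the brute-force information argmax", {
  for (seed in 1:6) {
    bank <- synthetic_item_bank(n_items = sample(4:10, 1), seed = seed)
    # first item at theta = 0: brute-force info over the whole bank
    info0 <- vapply(seq_len(nrow(bank)), function(j) {
      oracle_item_info(bank$discrimination[j], bank$thresholds[[j]], 0)
    }, numeric(1))
    expect_identical(select_next_item(tibble::tibble(linkId = character(),
                                                     score = integer()),
                                      bank, 0),
                     bank$linkId[which.max(info0)])
    # and at arbitrary estimates after partial administration
    for (theta in c(-1.7, -0.3, 0.9, 2.2)) {
      admin <- tibble::tibble(linkId = bank$linkId[1], score = 1L)
      remaining <- setdiff(bank$linkId, admin$linkId)
      info <- vapply(remaining, function(id) {
        j <- match(id, bank$linkId)
        oracle_item_info(bank$discrimination[j], bank$thresholds[[j]], theta)
      }, numeric(1))
      expect_identical(select_next_item(admin, bank, theta),
                       remaining[which.max(info)],
                       label = paste("seed", seed, "theta", theta))
    }
  }
})

test_that("analytic item information agrees with numerical differentiation", {
  bank <- synthetic_item_bank(n_items = 5, seed = 3)
  grid <- seq(-3, 3, by = 0.5)
  for (j in seq_len(nrow(bank))) {
    got <- grm_item_information(bank$discrimination[j], bank$thresholds[[j]],
                                grid)
    want <- vapply(grid, function(th) {
      oracle_item_info(bank$discrimination[j], bank$thresholds[[j]], th)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("precision accumulates as items are administered", {
  # Fisher information is additive over items, so cumulative test
  # information is strictly increasing; the EAP posterior SD in turn falls
  # well below the prior SD of 1 and ends below any intermediate plateau.
  # (Strict step-wise SD monotonicity does not hold for EAP with discrete
  # responses — a surprising answer can widen the posterior slightly — so
  # the guaranteed quantities are what is asserted.)
  withr::local_seed(31)
  for (rep in 1:20) {
    bank <- synthetic_item_bank(n_items = 8, seed = rep)
    scores <- vapply(bank$thresholds,
                     function(b) sample.int(length(b) + 1, 1) - 1L, 0L)
    ests <- purrr::map(seq_len(nrow(bank)), function(k) {
      eap_estimate(tibble::tibble(linkId = bank$linkId[1:k],
                                  score = scores[1:k]), bank)
    })
    ses <- vapply(ests, `[[`, 0, "se")
    infos <- vapply(seq_len(nrow(bank)), function(k) {
      theta <- ests[[nrow(bank)]]$theta
      sum(vapply(1:k, function(j) {
        grm_item_information(bank$discrimination[j], bank$thresholds[[j]],
                             theta)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(infos) > 0), label = paste("information, run", rep))
    expect_lt(ses[1], 1)                       # first item beats the prior
    expect_lt(ses[length(ses)], ses[1])        # net precision gain
    # and the trajectory agrees with the dense-grid oracle throughout
    k <- sample(2:nrow(bank), 1)
    orc <- oracle_posterior(tibble::tibble(linkId = bank$linkId[1:k],
                                           score = scores[1:k]), bank)
    expect_equal(ses[k], orc$se, tolerance = 0.02)
  }
})

test_that("the service enforces its session protocol", {
  bank <- synthetic_item_bank(n_items = 3, seed = 11)
  srv <- adaptive_service(bank, se_threshold = 0)
  cfg <- pghd_config()
  no_uuid <- as_fhir_resource(list(resourceType = "QuestionnaireResponse",
                                   status = "in-progress"))
  expect_error(next_question(srv, no_uuid), class = "pghd_error_session")

  # answers under an unknown uuid (after first call semantics) are refused
  stray <- as_fhir_resource(list(
    resourceType = "QuestionnaireResponse", status = "in-progress",
    identifier = list(system = cfg$session_id_system, value = "ghost"),
    item = list(list(linkId = "itm-01",
                     answer = list(list(valueCoding = bank$options[[1]][[1]]))))))
  expect_error(next_question(srv, stray), class = "pghd_error_session")

  # an answer to an item the service never issued is a protocol violation
  first <- next_question(srv, as_fhir_resource(list(
    resourceType = "QuestionnaireResponse", status = "in-progress",
    identifier = list(system = cfg$session_id_system, value = "s1"))))
  issued <- first$contained[[1]]$item[[1]]$linkId
  other <- setdiff(bank$linkId, issued)[1]
  bad <- unclass(first)
  j <- match(other, bank$linkId)
  bad$item <- list(list(linkId = other,
                        answer = list(list(valueCoding = bank$options[[j]][[1]]))))
  expect_error(next_question(srv, as_fhir_resource(bad)),
               class = "pghd_error_protocol")
})

test_that("dumping and restoring the session table between calls leaves the
           transcript unchanged", {
  bank <- synthetic_item_bank(n_items = 4, seed = 6)
  cfg <- pghd_config()

  drive <- function(restore_between_calls) {
    srv <- adaptive_service(bank, se_threshold = 0)
    qr <- list(resourceType = "QuestionnaireResponse", status = "in-progress",
               identifier = list(system = cfg$session_id_system,
                                 value = "stateless-check"))
    transcript <- list()
    repeat {
      if (restore_between_calls) {
        dumped <- jsonlite::fromJSON(
          jsonlite::toJSON(service_state(srv), auto_unbox = TRUE, digits = NA),
          simplifyVector = FALSE)
        srv <- service_restore(dumped, bank, se_threshold = 0)
      }
      resp <- next_question(srv, as_fhir_resource(qr))
      transcript <- c(transcript, list(fhir_serialize(resp)))
      if (identical(resp$status, "completed")) return(transcript)
      new_item <- resp$contained[[1]]$item[[length(resp$contained[[1]]$item)]]
      qr <- unclass(resp)
      qr$item <- c(qr$item %||% list(), list(list(
        linkId = new_item$linkId,
        answer = list(list(valueCoding = new_item$answerOption[[2]]$valueCoding)))))
    }
  }
  expect_identical(drive(TRUE), drive(FALSE))
})
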