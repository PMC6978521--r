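#' @title Reference computer-adaptive questionnaire service
#' @description
#' A deterministic, offline stand-in for an external computer-adaptive
#' survey provider. Items follow the graded response model: item j with
#' discrimination a_j and strictly increasing thresholds b_j1 < ... < b_jm
#' gives cumulative probabilities P*_k(theta) = logistic(a_j (theta - b_jk))
#' and category probabilities P_k = P*_k - P*_{k+1}. The latent trait is
#' scored by expected a posteriori (EAP) under a standard-normal prior on a
#' fixed 61-point quadrature grid over [-4, 4]; the next item administered
#' maximizes Fisher information at the current estimate; the session stops
#' when the posterior SD drops to the configured threshold (default 0.3) or
#' the bank is exhausted. The final trait is embedded in the completed
#' response as a T-score (50 + 10 theta) extension. These choices are this
#' package's own — the model stands in for an external black box.
#' @name adaptive_service_model
NULL

#' Construct a synthetic item bank
#'
#' @param n_items Number of items.
#' @param n_options Response options per item (thresholds = options - 1).
#' @param seed RNG seed; identical seeds give identical banks.
#' @return Item-bank tibble: `linkId`, `text`, `discrimination`,
#'   `thresholds` (list-column, strictly increasing), `options`
#'   (list-column of codings with 0-based scores).
#' @export
synthetic_item_bank <- function(n_items = 8, n_options = 5, seed = 1L) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_items), function(i) {
      a <- stats::runif(1, 0.8, 2.5)
      centre <- stats::runif(1, -2, 2)
      b <- sort(centre + cumsum(stats::runif(n_options - 1, 0.3, 0.8)) -
                  0.55 * (n_options - 1) / 2)
      list(linkId = sprintf("itm-%02d", i),
           text = sprintf("Synthetic bank item %d", i),
           discrimination = a, thresholds = b,
           options = purrr::map(seq_len(n_options) - 1L, function(k) {
             list(system = "urn:pghdflow:adaptive-option",
                  code = sprintf("itm-%02d-opt-%d", i, k),
                  display = sprintf("Option %d", k))
           }))
    })
  })
  tibble::tibble(
    linkId = vapply(rows, `[[`, "", "linkId"),
    text = vapply(rows, `[[`, "", "text"),
    discrimination = vapply(rows, `[[`, 0, "discrimination"),
    thresholds = purrr::map(rows, "thresholds"),
    options = purrr::map(rows, "options")
  )
}

#' Read an item bank from its JSON file
#'
#' Schema: array of objects `{linkId, text, discrimination, thresholds:
#' [...], options: [{system, code, display}, ...]}`.
#'
#' @param path JSON file path.
#' @return Item-bank tibble.
#' @export
read_item_bank <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble::tibble(
    linkId = vapply(raw, `[[`, "", "linkId"),
    text = vapply(raw, `[[`, "", "text"),
    discrimination = vapply(raw, function(r) as.numeric(r$discrimination), 0),
    thresholds = purrr::map(raw, function(r) as.numeric(unlist(r$thresholds))),
    options = purrr::map(raw, "options")
  )
}

# Cumulative P*_k(theta), k = 1..m, plus virtual P*_0 = 1, P*_{m+1} = 0
grm_cumulative <- function(a, thresholds, theta) {
  vapply(thresholds, function(b) stats::plogis(a * (theta - b)),
         numeric(length(theta)))
}

#' Graded-response category probabilities
#'
#' @param a Discrimination.
#' @param thresholds Increasing threshold vector (length m).
#' @param theta Trait values (vectorized).
#' @return Matrix `length(theta) x (m + 1)` of category probabilities
#'   (scores 0..m); rows sum to 1.
#' @export
grm_category_probs <- function(a, thresholds, theta) {
  ps <- matrix(grm_cumulative(a, thresholds, theta), nrow = length(theta))
  cbind(1, ps) - cbind(ps, 0)
}

#' Fisher information of a graded-response item
#'
#' \eqn{I(\theta) = \sum_k (dP_k/d\theta)^2 / P_k} with
#' \eqn{dP_k/d\theta = a (P^*_k(1-P^*_k) - P^*_{k+1}(1-P^*_{k+1}))}.
#'
#' @inheritParams grm_category_probs
#' @return Numeric vector of information values at `theta`.
#' @export
grm_item_information <- function(a, thresholds, theta) {
  ps <- cbind(1, matrix(grm_cumulative(a, thresholds, theta),
                        nrow = length(theta)), 0)
  P <- ps[, -ncol(ps), drop = FALSE] - ps[, -1, drop = FALSE]
  d <- a * (ps[, -ncol(ps), drop = FALSE] * (1 - ps[, -ncol(ps), drop = FALSE]) -
            ps[, -1, drop = FALSE] * (1 - ps[, -1, drop = FALSE]))
  rowSums(d^2 / pmax(P, 1e-12))
}

#' EAP estimate of the latent trait
#'
#' Expected a posteriori mean and posterior SD under a standard-normal
#' prior, evaluated on a fixed quadrature grid. Deterministic given the
#' administered set and bank. With nothing administered it returns the
#' prior: `(0, 1)`.
#'
#' @param administered Tibble with columns `linkId` and `score` (0-based
#'   option scores).
#' @param bank Item-bank tibble.
#' @param grid Quadrature nodes (default 61 points on `[-4, 4]`).
#' @return Named list `theta`, `se`.
#' @export
eap_estimate <- function(administered, bank,
                         grid = seq(-4, 4, length.out = 61)) {
  if (is.null(administered) || nrow(administered) == 0) {
    return(list(theta = 0, se = 1))
  }
  logpost <- stats::dnorm(grid, log = TRUE)
  for (i in seq_len(nrow(administered))) {
    j <- match(administered$linkId[i], bank$linkId)
    if (is.na(j)) stop(pghd_error("protocol",
                                  paste0("answered item not in bank: ",
                                         administered$linkId[i])))
    probs <- grm_category_probs(bank$discrimination[j], bank$thresholds[[j]],
                                grid)
    logpost <- logpost + log(pmax(probs[, administered$score[i] + 1], 1e-300))
  }
  w <- exp(logpost - max(logpost))
  theta <- sum(grid * w) / sum(w)
  se <- sqrt(sum((grid - theta)^2 * w) / sum(w))
  list(theta = theta, se = se)
}

#' Pick the next item: maximal Fisher information at the current estimate
#'
#' @param administered Tibble (`linkId`, `score`) of answered items.
#' @param bank Item-bank tibble.
#' @param theta Current trait estimate.
#' @return The linkId of the most informative unadministered item, or `NA`
#'   when the bank is exhausted. Ties break by bank order.
#' @export
select_next_item <- function(administered, bank, theta) {
  remaining <- setdiff(bank$linkId, administered$linkId)
  if (length(remaining) == 0) return(NA_character_)
  info <- vapply(remaining, function(id) {
    j <- match(id, bank$linkId)
    grm_item_information(bank$discrimination[j], bank$thresholds[[j]], theta)
  }, numeric(1))
  remaining[which.max(info)]
}

#' Start a reference adaptive service instance
#'
#' The service is stateless in the FHIR sense: per-session state is keyed
#' only by the session UUID the client sends, and the whole session table
#' can be serialized and restored between calls without changing any
#' transcript.
#'
#' @param bank Item-bank tibble (see [synthetic_item_bank()]).
#' @param se_threshold Stop once the posterior SD is at or below this
#'   (default 0.3). Set to 0 to force bank exhaustion.
#' @param credentials Length-2 character vector checked against the
#'   client's Basic authorization header.
#' @param online Simulated reachability; an offline service raises a
#'   transport error without touching state.
#' @return An `adaptive_service` handle.
#' @export
adaptive_service <- function(bank = synthetic_item_bank(),
                             se_threshold = 0.3,
                             credentials = c("pghd", "pghd-secret"),
                             online = TRUE) {
  env <- new.env(parent = emptyenv())
  env$sessions <- list()
  env$online <- online
  env$transcript <- list()
  structure(list(env = env, bank = bank, se_threshold = se_threshold,
                 credentials = credentials),
            class = "adaptive_service")
}

#' @export
print.adaptive_service <- function(x, ...) {
  cat("<adaptive_service> ", nrow(x$bank), "-item bank, SE threshold ",
      x$se_threshold, ", ", length(x$env$sessions), " sessions\n", sep = "")
  invisible(x)
}

#' Toggle simulated reachability
#' @param service An [adaptive_service()].
#' @param online Logical.
#' @export
service_set_online <- function(service, online) {
  service$env$online <- isTRUE(online)
  invisible(service)
}

# HTTP-shaped entry point: JSON body + Authorization header in, JSON out.
# Kept as the single adapter between client and service so the wire shape
# lives in one place.
adaptive_call <- function(service, body_json, auth_header) {
  if (!isTRUE(service$env$online)) {
    stop(pghd_error("transport", "adaptive service unreachable"))
  }
  expected <- paste0("Basic ",
                     jsonlite::base64_enc(paste(service$credentials,
                                                collapse = ":")))
  if (!identical(auth_header, expected)) {
    stop(pghd_error("auth", "adaptive service rejected the credentials"))
  }
  service$env$transcript <- c(service$env$transcript, list(body_json))
  resp <- next_question(service, fhir_parse(body_json))
  out <- fhir_serialize(resp)
  service$env$transcript <- c(service$env$transcript, list(out))
  out
}

#' The next-question operation
#'
#' Records any newly answered item on the session keyed by the payload's
#' session UUID, re-estimates the trait, and either appends exactly one new
#' item (the unadministered bank item with maximal information at the
#' current estimate, carried in the contained Questionnaire) with status
#' in-progress, or returns status completed with the final T-score
#' embedded.
#'
#' @param service An [adaptive_service()].
#' @param in_progress The in-progress QuestionnaireResponse
#'   `fhir_resource`.
#' @return The updated QuestionnaireResponse `fhir_resource`.
#' @export
next_question <- function(service, in_progress) {
  qr <- as_fhir_resource(in_progress)
  uuid <- qr$identifier$value
  if (is.null(uuid) ||
      !identical(qr$identifier$system, pghd_config()$session_id_system)) {
    stop(pghd_error("session", "payload carries no session identifier"))
  }
  st <- service$env$sessions[[uuid]]
  answered <- purrr::map_chr(qr$item %||% list(), "linkId")
  if (is.null(st)) {
    if (length(answered) > 0) {
      stop(pghd_error("session", paste0("unknown session: ", uuid)))
    }
    st <- list(administered = tibble::tibble(linkId = character(),
                                             score = integer()),
               issued = character(), finished = FALSE)
  }
  if (isTRUE(st$finished)) {
    stop(pghd_error("session", "session already completed"))
  }
  new_ids <- setdiff(answered, st$administered$linkId)
  for (id in new_ids) {
    if (!id %in% st$issued) {
      stop(pghd_error("protocol", paste0("answer to an item never issued: ", id)))
    }
    it <- purrr::detect(qr$item, function(x) identical(x$linkId, id))
    score <- score_from_answer(service$bank, id, it)
    st$administered <- dplyr::bind_rows(st$administered,
                                        tibble::tibble(linkId = id,
                                                       score = score))
  }
  est <- eap_estimate(st$administered, service$bank)
  done <- (nrow(st$administered) > 0 && est$se <= service$se_threshold) ||
    nrow(st$administered) == nrow(service$bank)
  if (done) {
    st$finished <- TRUE
    service$env$sessions[[uuid]] <- st
    out <- unclass(qr)
    out$status <- "completed"
    out$extension <- c(out$extension %||% list(),
                       list(list(url = pghd_config()$score_extension_url,
                                 valueDecimal = 50 + 10 * est$theta)))
    return(as_fhir_resource(out))
  }
  nxt <- select_next_item(st$administered, service$bank, est$theta)
  st$issued <- union(st$issued, nxt)
  service$env$sessions[[uuid]] <- st
  j <- match(nxt, service$bank$linkId)
  new_item <- list(linkId = nxt, text = service$bank$text[j], type = "choice",
                   answerOption = purrr::map(service$bank$options[[j]],
                                             function(o) list(valueCoding = o)))
  out <- unclass(qr)
  contained_q <- if (length(out$contained %||% list()) > 0) {
    out$contained[[1]]
  } else {
    list(resourceType = "Questionnaire", id = "issued-items",
         status = "active", item = list())
  }
  contained_q$item <- c(contained_q$item, list(new_item))
  out$contained <- list(contained_q)
  as_fhir_resource(out)
}

score_from_answer <- function(bank, id, item) {
  j <- match(id, bank$linkId)
  if (is.na(j)) stop(pghd_error("protocol", paste0("item not in bank: ", id)))
  coding <- item$answer[[1]]$valueCoding
  codes <- vapply(bank$options[[j]], `[[`, "", "code")
  k <- match(coding$code %||% "", codes)
  if (is.na(k)) stop(pghd_error("protocol",
                                paste0("answer coding not an option of ", id)))
  k - 1L
}

#' Serialize / restore the service's session table
#'
#' Supports the statelessness contract: dumping and restoring state between
#' calls leaves transcripts unchanged.
#'
#' @param service An [adaptive_service()].
#' @return `service_state()`: a plain list (JSON-serializable);
#'   `service_restore()`: a new `adaptive_service` with the same bank,
#'   threshold and restored sessions.
#' @export
service_state <- function(service) {
  purrr::map(service$env$sessions, function(st) {
    list(administered = list(linkId = st$administered$linkId,
                             score = st$administered$score),
         issued = st$issued, finished = st$finished)
  })
}

#' @rdname service_state
#' @param state A list from [service_state()].
#' @inheritParams adaptive_service
#' @export
service_restore <- function(state, bank, se_threshold = 0.3,
                            credentials = c("pghd", "pghd-secret")) {
  srv <- adaptive_service(bank, se_threshold, credentials)
  srv$env$sessions <- purrr::map(state, function(st) {
    list(administered = tibble::tibble(
      linkId = as.character(unlist(st$administered$linkId) %||% character()),
      score = as.integer(unlist(st$administered$score) %||% integer())),
      issued = as.character(unlist(st$issued) %||% character()),
      finished = isTRUE(st$finished))
  })
  srv
}

#' Transcript of every payload the service has exchanged
#' @param service An [adaptive_service()].
#' @return Character vector of serialized payloads.
#' @export
service_transcript <- function(service) {
  unlist(service$env$transcript) %||% character()
}
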