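#' In-memory mock FHIR store
#'
#' A test double for the health system's FHIR server: it implements exactly
#' the interactions the workflow uses (create, read, search by `patient`/
#' `status`, transaction) behind a stub bearer-token check, and keeps an
#' append-only request log so tests can assert, e.g., that withholding
#' consent produces zero store interactions. Two independently configured
#' instances emulate the dual-sandbox reusability setting.
#'
#' @param base_url Base URL token identifying the instance (no networking
#'   happens; the URL is an identity and appears in the log).
#' @param token Static bearer token the instance expects.
#' @return A `mock_store` handle with reference semantics.
#' @examples
#' st <- mock_store("http://a.example/fhir", "tok-a")
#' p <- store_interact(st, "create", "Patient",
#'                     list(resourceType = "Patient", name = list(list(family = "X"))))
#' store_interact(st, "read", paste0("Patient/", p$id))$id
#' @export
mock_store <- function(base_url = "http://store-a.example/fhir",
                       token = "token-a") {
  env <- new.env(parent = emptyenv())
  env$resources <- list()   # [[type]][[id]] -> element tree
  env$log <- list()         # append-only (verb, path, digest)
  env$counter <- 0L
  structure(list(env = env, base_url = base_url, token = token),
            class = "mock_store")
}

#' @export
print.mock_store <- function(x, ...) {
  n <- sum(vapply(x$env$resources, length, integer(1)))
  cat("<mock_store> ", x$base_url, " — ", n, " resources, ",
      length(x$env$log), " logged interactions\n", sep = "")
  invisible(x)
}

#' Interact with a mock store
#'
#' @param store A [mock_store()] handle.
#' @param verb One of `create`, `read`, `search`, `transaction`.
#' @param target For `create`: a resourceType; for `read`: `"Type/id"`; for
#'   `search`: a resourceType (with `params`); ignored for `transaction`.
#' @param payload The resource to create, or the transaction Bundle.
#' @param params Named list of search parameters; supported: `patient`,
#'   `status`.
#' @param token Bearer token; defaults to the configured profile token.
#' @return `create`: the persisted resource with its server-assigned id;
#'   `read`: the resource; `search`: a searchset Bundle; `transaction`: a
#'   transaction-response Bundle.
#' @export
store_interact <- function(store, verb, target = NULL, payload = NULL,
                           params = list(), token = store$token) {
  stopifnot(inherits(store, "mock_store"))
  if (!identical(token, store$token)) {
    stop(pghd_error("auth", paste0("bad bearer token for ", store$base_url)))
  }
  path <- switch(verb,
    create = paste0("POST ", target),
    read = paste0("GET ", target),
    search = paste0("GET ", target, search_query(params)),
    transaction = "POST /",
    stop(pghd_error("verb", paste0("unsupported interaction: ", verb)))
  )
  digest <- if (is.null(payload)) "" else rlang::hash(fhir_serialize(as_fhir_resource(payload)))
  store$env$log <- c(store$env$log, list(list(verb = verb, path = path,
                                              digest = digest)))
  switch(verb,
    create = store_create(store, target, payload),
    read = store_read(store, target),
    search = store_search(store, target, params),
    transaction = store_transaction(store, payload)
  )
}

search_query <- function(params) {
  if (length(params) == 0) return("")
  paste0("?", paste(names(params), unlist(params), sep = "=", collapse = "&"))
}

store_create <- function(store, type, resource, validate = TRUE) {
  resource <- as_fhir_resource(resource)
  if (!identical(resource$resourceType, type)) {
    stop(pghd_error("structure", "payload resourceType does not match target"))
  }
  if (validate) {
    iss <- fhir_check_structure(resource)
    if (!fhir_conformant(iss)) {
      stop(pghd_error("invalid-resource",
                      paste0("resource rejected: ",
                             paste(iss$code[iss$severity == "error"],
                                   iss$path[iss$severity == "error"],
                                   collapse = "; "))))
    }
  }
  if (is.null(resource[["id"]]) ||
      !is.null(store$env$resources[[type]][[resource[["id"]]]])) {
    store$env$counter <- store$env$counter + 1L
    resource[["id"]] <- paste0(tolower(type), "-", store$env$counter)
  }
  if (is.null(store$env$resources[[type]])) store$env$resources[[type]] <- list()
  store$env$resources[[type]][[resource[["id"]]]] <- unclass(fhir_canonicalize(resource))
  resource
}

store_read <- function(store, target) {
  bits <- strsplit(target, "/", fixed = TRUE)[[1]]
  res <- store$env$resources[[bits[1]]][[bits[2]]]
  if (is.null(res)) {
    stop(pghd_error("not-found", paste0("no ", target, " in ", store$base_url)))
  }
  as_fhir_resource(res)
}

store_search <- function(store, type, params) {
  pool <- store$env$resources[[type]] %||% list()
  keep <- purrr::keep(pool, function(r) {
    ok <- TRUE
    if (!is.null(params$patient)) {
      want <- paste0("Patient/", sub("^Patient/", "", params$patient))
      subj <- r$subject$reference %||% ""
      ok <- ok && identical(subj, want)
    }
    if (!is.null(params$status)) ok <- ok && identical(r$status, params$status)
    ok
  })
  if (length(keep) > 0) keep <- keep[order(names(keep))]
  as_fhir_resource(list(
    resourceType = "Bundle", type = "searchset",
    total = length(keep),
    entry = unname(purrr::map(keep, function(r) {
      list(fullUrl = paste0(store$base_url, "/", type, "/", r[["id"]]), resource = r)
    }))
  ))
}

# Atomic: validate every entry first; one invalid entry -> nothing persisted
store_transaction <- function(store, bundle) {
  bundle <- as_fhir_resource(bundle)
  if (!identical(bundle$type, "transaction")) {
    stop(pghd_error("structure", "transaction verb requires a Bundle of type transaction"))
  }
  entries <- bundle$entry %||% list()
  outcomes <- purrr::map(entries, function(e) {
    r <- e$resource
    if (is.null(r)) return(list(ok = FALSE, detail = "entry without resource"))
    iss <- tryCatch(fhir_check_structure(as_fhir_resource(r)),
                    error = function(err) NULL)
    if (is.null(iss)) return(list(ok = FALSE, detail = "unparseable entry"))
    errs <- iss[iss$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      return(list(ok = FALSE,
                  detail = paste(errs$code, errs$path, collapse = "; ")))
    }
    list(ok = TRUE, detail = "")
  })
  ok <- vapply(outcomes, `[[`, logical(1), "ok")
  if (!all(ok)) {
    stop(pghd_error("transaction",
                    paste0("transaction rolled back; failing entries: ",
                           paste(which(!ok), collapse = ", "), " (",
                           paste(vapply(outcomes[!ok], `[[`, "", "detail"),
                                 collapse = " | "), ")")))
  }
  resp <- purrr::map(entries, function(e) {
    r <- as_fhir_resource(e$resource)
    stored <- store_create(store, r$resourceType, r, validate = FALSE)
    list(response = list(status = "201 Created",
                         location = paste0(stored$resourceType, "/", stored[["id"]])))
  })
  as_fhir_resource(list(resourceType = "Bundle", type = "transaction-response",
                        entry = resp))
}

#' The store's append-only request log
#'
#' @param store A [mock_store()] handle.
#' @return Tibble with one row per interaction: `verb`, `path`, `digest`.
#' @export
store_log <- function(store) {
  tibble::tibble(
    verb = vapply(store$env$log, `[[`, "", "verb"),
    path = vapply(store$env$log, `[[`, "", "path"),
    digest = vapply(store$env$log, `[[`, "", "digest")
  )
}

#' Seed a store with a list of resources (bypasses the request log)
#'
#' Fixture loading helper: persists each resource as-is, keeping ids.
#'
#' @param store A [mock_store()] handle.
#' @param resources List of `fhir_resource` trees (ids preserved).
#' @return The store, invisibly.
#' @export
store_seed <- function(store, resources) {
  for (r in resources) {
    r <- as_fhir_resource(r)
    ty <- r$resourceType
    if (is.null(r[["id"]])) {
      store$env$counter <- store$env$counter + 1L
      r[["id"]] <- paste0(tolower(ty), "-", store$env$counter)
    }
    if (is.null(store$env$resources[[ty]])) store$env$resources[[ty]] <- list()
    store$env$resources[[ty]][[r[["id"]]]] <- unclass(fhir_canonicalize(r))
  }
  invisible(store)
}

#' All resources of one type currently persisted
#'
#' @param store A [mock_store()] handle.
#' @param type Resource type token.
#' @return Named list (by id) of element trees.
#' @export
store_resources <- function(store, type) {
  res <- store$env$resources[[type]] %||% list()
  if (length(res) > 0) res <- res[order(names(res))]
  res
}
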