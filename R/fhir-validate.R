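#' Structural and cardinality validation of a FHIR resource
#'
#' Walks the element tree against the shipped R4 element-definition table and
#' reports one issue per violated constraint. Issue codes form a closed set:
#' `cardinality-min` (required element absent), `cardinality-max` (more
#' repetitions than allowed, or several variants of one choice element),
#' `wrong-type` (JSON shape or primitive type does not match the element's
#' datatype), and `unknown-element` (warning: element retained but not part
#' of the supported definitions).
#'
#' @param resource A `fhir_resource` element tree (see [fhir_parse()]).
#' @param defs Element-definition table; defaults to the shipped R4 subset.
#' @return A tibble with columns `severity` (`error`/`warning`), `code`,
#'   `path` (dotted, with `[i]` indices into repeating elements), `detail`.
#'   Zero rows iff the resource is conformant (warnings aside, zero
#'   error-severity rows).
#' @examples
#' q <- fhir_parse('{"resourceType":"Questionnaire","id":"q1"}')
#' fhir_check_structure(q)   # flags missing Questionnaire.status
#' @export
fhir_check_structure <- function(resource, defs = fhir_element_definitions()) {
  if (!is.list(resource) || is.null(resource$resourceType)) {
    stop(pghd_error("structure", "not a FHIR resource element tree"))
  }
  rt <- resource$resourceType
  if (!rt %in% fhir_supported_types()) {
    stop(pghd_error("unsupported-type", paste0("unsupported resourceType: ", rt)))
  }
  issues <- check_node(unclass(resource), rt, rt, is_root = TRUE)
  tibble::tibble(
    severity = vapply(issues, `[[`, "", "severity"),
    code = vapply(issues, `[[`, "", "code"),
    path = vapply(issues, `[[`, "", "path"),
    detail = vapply(issues, `[[`, "", "detail")
  )
}

#' Do any issues reach error severity?
#'
#' @param issues Tibble from [fhir_check_structure()].
#' @return `TRUE` if no error-severity rows.
#' @export
fhir_conformant <- function(issues) {
  !any(issues$severity == "error")
}

issue <- function(severity, code, path, detail) {
  list(list(severity = severity, code = code, path = path, detail = detail))
}

check_node <- function(node, def_prefix, inst_path, is_root = FALSE) {
  out <- list()
  if (!is.list(node) || (length(node) > 0 && is.null(names(node)))) {
    return(issue("error", "wrong-type", inst_path, "expected JSON object"))
  }
  defs <- fhir_children(def_prefix)
  keys <- names(node)

  # required elements (choice bases count any expansion)
  req <- defs[defs$min >= 1, , drop = FALSE]
  for (i in seq_len(nrow(req))) {
    d <- req[i, ]
    present <- if (d$choice) {
      any(!is.na(vapply(keys, function(k) match_choice_one(k, d), integer(1))))
    } else {
      d$name %in% keys
    }
    if (!present) {
      out <- c(out, issue("error", "cardinality-min",
                          paste0(inst_path, ".", d$name),
                          paste0("mandatory element missing (", d$min, "..",
                                 ifelse(is.infinite(d$max), "*", d$max), ")")))
    }
  }

  # choice elements populated with more than one variant
  for (j in which(defs$choice)) {
    d <- defs[j, ]
    hits <- keys[!is.na(vapply(keys, function(k) match_choice_one(k, d), integer(1)))]
    if (length(hits) > 1) {
      out <- c(out, issue("error", "wrong-type",
                          paste0(inst_path, ".", d$name),
                          paste0("choice element populated with multiple variants: ",
                                 paste(hits, collapse = ", "))))
    }
  }

  for (k in keys) {
    v <- node[[k]]
    ipath <- paste0(inst_path, ".", k)
    if (is_root && k %in% c("resourceType", "implicitRules", "language")) {
      if (!is_primitive_ok(v, "string")) {
        out <- c(out, issue("error", "wrong-type", ipath, "expected string"))
      }
      next
    }
    if (is_root && k == "text") {
      out <- c(out, check_node(v, "Narrative", ipath))
      next
    }
    if (is_root && k == "meta") {
      out <- c(out, check_node(v, "Meta", ipath))
      next
    }
    if (is_root && k == "contained") {
      out <- c(out, check_array_of(v, "Resource", ipath))
      next
    }
    if (k == "id") {
      if (!is_primitive_ok(v, "string")) {
        out <- c(out, issue("error", "wrong-type", ipath, "id must be a string"))
      }
      next
    }
    if (k %in% c("extension", "modifierExtension")) {
      out <- c(out, check_array_of(v, "Extension", ipath))
      next
    }
    j <- match_def(k, defs)
    if (is.na(j)) {
      out <- c(out, issue("warning", "unknown-element", ipath,
                          paste0("element not in the supported ", def_prefix,
                                 " definitions; retained verbatim")))
      next
    }
    d <- defs[j, ]
    child <- child_def_prefix(d, k)
    ty <- concrete_type(d, k)
    if (d$max > 1) {
      if (!is.list(v) || !is.null(names(v))) {
        out <- c(out, issue("error", "wrong-type", ipath,
                            "repeating element must be a JSON array"))
        next
      }
      if (length(v) > d$max) {
        out <- c(out, issue("error", "cardinality-max", ipath,
                            paste0("at most ", d$max, " repetitions allowed")))
      }
      if (d$min >= 1 && length(v) < d$min) {
        out <- c(out, issue("error", "cardinality-min", ipath,
                            paste0("at least ", d$min, " repetitions required")))
      }
      for (i in seq_along(v)) {
        out <- c(out, check_value(v[[i]], ty, child,
                                  paste0(ipath, "[", i, "]")))
      }
    } else {
      if (is.list(v) && is.null(names(v)) && length(v) != 0) {
        out <- c(out, issue("error", "cardinality-max", ipath,
                            "element with max cardinality 1 given as an array"))
        next
      }
      out <- c(out, check_value(v, ty, child, ipath))
    }
  }
  out
}

check_value <- function(v, type, child_prefix, ipath) {
  if (identical(child_prefix, "Resource")) {
    if (!is.list(v) || is.null(v$resourceType)) {
      return(issue("error", "wrong-type", ipath, "expected an inline resource"))
    }
    if (!v$resourceType %in% fhir_supported_types()) {
      return(issue("error", "wrong-type", ipath,
                   paste0("unsupported inline resourceType: ", v$resourceType)))
    }
    return(check_node(v, v$resourceType, ipath, is_root = TRUE))
  }
  if (!is.null(child_prefix)) {
    return(check_node(v, child_prefix, ipath))
  }
  if (!is_primitive_ok(v, type)) {
    return(issue("error", "wrong-type", ipath,
                 paste0("expected FHIR primitive ", type)))
  }
  list()
}

check_array_of <- function(v, prefix, ipath) {
  if (!is.list(v) || !is.null(names(v))) {
    return(issue("error", "wrong-type", ipath, "expected a JSON array"))
  }
  out <- list()
  for (i in seq_along(v)) {
    p <- paste0(ipath, "[", i, "]")
    if (prefix == "Resource") {
      out <- c(out, check_value(v[[i]], NULL, "Resource", p))
    } else {
      out <- c(out, check_node(v[[i]], prefix, p))
    }
  }
  out
}

# concrete datatype token for a (possibly choice) definition and JSON key
concrete_type <- function(def, key) {
  if (!def$choice) return(def$types)
  base <- sub("\\[x\\]$", "", def$name)
  t <- substring(key, nchar(base) + 1)
  types <- strsplit(def$types, ",", fixed = TRUE)[[1]]
  types[match(tolower(t), tolower(types))]
}

match_choice_one <- function(key, def) {
  base <- sub("\\[x\\]$", "", def$name)
  if (!startsWith(key, base) || nchar(key) <= nchar(base)) return(NA_integer_)
  t <- substring(key, nchar(base) + 1)
  types <- strsplit(def$types, ",", fixed = TRUE)[[1]]
  if (any(tolower(types) == tolower(t))) 1L else NA_integer_
}

is_primitive_ok <- function(v, type) {
  if (is.na(type) || is.null(type)) return(FALSE)
  if (is.list(v) || length(v) != 1 || is.na(v)) return(FALSE)
  switch(type,
    boolean = is.logical(v),
    integer = is.numeric(v) && abs(v - round(v)) < 1e-9,
    positiveInt = is.numeric(v) && abs(v - round(v)) < 1e-9 && v >= 1,
    unsignedInt = is.numeric(v) && abs(v - round(v)) < 1e-9 && v >= 0,
    decimal = is.numeric(v),
    date = is.character(v) && grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", v),
    dateTime = is.character(v) &&
      grepl("^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:\\d{2})?)?)?)?$", v),
    instant = is.character(v) &&
      grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:\\d{2})$", v),
    time = is.character(v) && grepl("^\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?$", v),
    is.character(v)   # string, code, id, uri, url, canonical, markdown, ...
  )
}

#' Render validation issues as a FHIR OperationOutcome
#'
#' @param issues Tibble from [fhir_check_structure()] or
#'   [validate_response()].
#' @return A `fhir_resource` of type OperationOutcome; when there are no
#'   issues it carries a single informational "all OK" issue.
#' @export
as_operation_outcome <- function(issues) {
  if (nrow(issues) == 0) {
    entries <- list(list(severity = "information", code = "informational",
                         diagnostics = "no issues detected"))
  } else {
    entries <- purrr::pmap(issues, function(severity, code, path = NULL,
                                            detail, ...) {
      it <- list(severity = severity,
                 code = if (code %in% c("cardinality-min", "cardinality-max")) "required"
                        else if (code == "unknown-element") "informational"
                        else "structure",
                 diagnostics = paste0(code, ": ", detail))
      if (!is.null(path)) it$expression <- list(path)
      it
    })
  }
  as_fhir_resource(list(resourceType = "OperationOutcome", issue = entries))
}
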