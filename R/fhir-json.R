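#' @title FHIR R4 JSON parsing and canonical serialization
#' @description
#' Resources are represented as *element trees*: named lists mirroring the
#' FHIR JSON structure, with JSON arrays as unnamed lists and JSON scalars as
#' length-one vectors. All numbers are normalized to double (JSON does not
#' distinguish integer from decimal). Serialization is canonical: object keys
#' are emitted in FHIR definition order so that equal trees give byte-equal
#' JSON, which keeps golden files and the dual-store comparison bit-stable.
#' @name fhir_json
NULL

#' Supported FHIR R4 resource types
#'
#' The closed subset of resource types the workflow touches. Any other
#' `resourceType` is a hard error, not a silent pass.
#'
#' @return Character vector of resource type tokens.
#' @export
fhir_supported_types <- function() {
  c(
    "Questionnaire", "QuestionnaireResponse", "ServiceRequest", "Observation",
    "DocumentReference", "Media", "ValueSet", "Bundle", "Patient",
    "Practitioner", "OperationOutcome"
  )
}

#' Parse a FHIR R4 JSON document into a resource element tree
#'
#' Unrecognized elements are retained verbatim (round-trip safe); they are
#' reported as warnings only by [fhir_check_structure()], never dropped.
#'
#' @param text A single string containing one FHIR JSON resource, or a path
#'   to a file holding one.
#' @return A `fhir_resource`: a named list element tree.
#' @examples
#' p <- fhir_parse('{"resourceType":"Patient","id":"p1"}')
#' p$id
#' @export
fhir_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("^\\s*\\{", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  tree <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop(pghd_error("parse", paste0("malformed JSON: ", conditionMessage(e))))
  )
  as_fhir_resource(tree)
}

#' Coerce an element tree to a `fhir_resource`
#'
#' @param tree A named list with a `resourceType` entry.
#' @return The tree, number-normalized, classed `fhir_resource`.
#' @export
as_fhir_resource <- function(tree) {
  if (!is.list(tree) || is.null(tree$resourceType)) {
    stop(pghd_error("structure", "document has no resourceType"))
  }
  rt <- tree$resourceType
  if (!is.character(rt) || length(rt) != 1) {
    stop(pghd_error("structure", "resourceType must be a single string"))
  }
  if (!rt %in% fhir_supported_types()) {
    stop(pghd_error("unsupported-type", paste0("unsupported resourceType: ", rt)))
  }
  tree <- normalize_numbers(tree)
  class(tree) <- c("fhir_resource", "list")
  tree
}

# JSON has one number type; make trees comparable with identical()
normalize_numbers <- function(x) {
  if (is.list(x)) {
    x[] <- lapply(x, normalize_numbers)
    x
  } else if (is.integer(x)) {
    as.double(x)
  } else {
    x
  }
}

#' Serialize a resource element tree to canonical FHIR JSON
#'
#' Keys are reordered into FHIR definition order (unknown keys keep their
#' original relative order after the known ones); output is UTF-8 with no
#' trailing whitespace. `fhir_parse(fhir_serialize(x))` reproduces the
#' canonicalized element tree exactly.
#'
#' @param resource A `fhir_resource` element tree.
#' @param pretty Pretty-print with indentation (default `FALSE`).
#' @return A single JSON string.
#' @export
fhir_serialize <- function(resource, pretty = FALSE) {
  stopifnot(is.list(resource))
  tree <- fhir_canonicalize(resource)
  out <- jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = pretty)
  sub("[ \t\r\n]+$", "", as.character(out))
}

#' Reorder an element tree's keys into FHIR definition order
#'
#' @param resource A `fhir_resource`.
#' @return The same tree with canonically ordered keys.
#' @export
fhir_canonicalize <- function(resource) {
  rt <- resource$resourceType
  out <- order_node(unclass(resource), rt, is_root = TRUE)
  class(out) <- c("fhir_resource", "list")
  out
}

# Element keys common to every complex node, in wire order
root_common_keys <- c("resourceType", "id", "meta", "implicitRules",
                      "language", "text", "contained")
node_common_keys <- c("id", "extension", "modifierExtension")

order_node <- function(node, def_prefix, is_root = FALSE) {
  if (!is.list(node) || is.null(names(node))) return(node)
  defs <- fhir_children(def_prefix)
  known <- defs$name
  head_keys <- if (is_root) c(root_common_keys, node_common_keys) else node_common_keys
  keys <- names(node)
  rank <- vapply(keys, function(k) {
    i <- match(k, head_keys)
    if (!is.na(i)) return(i)
    j <- match_def(k, defs)
    if (!is.na(j)) return(length(head_keys) + j)
    length(head_keys) + nrow(defs) + match(k, keys)
  }, numeric(1))
  node <- node[order(rank)]
  for (k in names(node)) {
    j <- match_def(k, defs)
    if (is.na(j)) {
      if (k == "contained" && is_root) {
        node[[k]] <- lapply(node[[k]], function(r) {
          if (is.list(r) && !is.null(r$resourceType)) {
            order_node(r, r$resourceType, is_root = TRUE)
          } else r
        })
      } else if (k == "extension" || k == "modifierExtension") {
        node[[k]] <- lapply(node[[k]], order_node, def_prefix = "Extension")
      } else if (k == "meta" && is_root) {
        node[[k]] <- order_node(node[[k]], "Meta")
      }
      next
    }
    d <- defs[j, ]
    child_prefix <- child_def_prefix(d, k)
    if (is.null(child_prefix)) next
    if (d$max > 1) {
      if (is.list(node[[k]]) && is.null(names(node[[k]]))) {
        node[[k]] <- lapply(node[[k]], function(el) {
          if (identical(child_prefix, "Resource") && is.list(el) &&
              !is.null(el$resourceType)) {
            order_node(el, el$resourceType, is_root = TRUE)
          } else {
            order_node(el, child_prefix)
          }
        })
      }
    } else if (is.list(node[[k]]) && !is.null(names(node[[k]]))) {
      if (identical(child_prefix, "Resource")) {
        node[[k]] <- order_node(node[[k]], node[[k]]$resourceType, is_root = TRUE)
      } else {
        node[[k]] <- order_node(node[[k]], child_prefix)
      }
    }
  }
  node
}

# defs: tibble of children of def_prefix; match a concrete JSON key against
# a definition row (exact name, or a choice expansion like valueQuantity)
match_def <- function(key, defs) {
  i <- match(key, defs$name)
  if (!is.na(i)) return(i)
  choice <- which(defs$choice)
  for (j in choice) {
    base <- sub("\\[x\\]$", "", defs$name[j])
    if (startsWith(key, base) && nchar(key) > nchar(base)) {
      t <- substring(key, nchar(base) + 1)
      types <- strsplit(defs$types[j], ",", fixed = TRUE)[[1]]
      if (tolower(t) %in% tolower(types) || capitalize(t) %in% types ||
          tolower(substring(t, 1, 1)) == substring(t, 1, 1)) {
        if (any(tolower(types) == tolower(t))) return(j)
      }
    }
  }
  NA_integer_
}

capitalize <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

# Where to descend for a child definition: a datatype name, a backbone path,
# "Resource" for inline resources, or NULL for primitives
child_def_prefix <- function(def, key) {
  ty <- def$types
  if (def$choice) {
    base <- sub("\\[x\\]$", "", def$name)
    t <- substring(key, nchar(base) + 1)
    types <- strsplit(ty, ",", fixed = TRUE)[[1]]
    ty <- types[match(tolower(t), tolower(types))]
    if (is.na(ty)) return(NULL)
  }
  if (startsWith(ty, "=")) return(substring(ty, 2))        # backbone recursion
  if (ty == "BackboneElement" || ty == "Element") return(def$path)
  if (ty == "Resource") return("Resource")
  if (ty %in% fhir_complex_types()) return(ty)
  NULL                                                      # primitive
}

#' Read / write NDJSON resource corpora
#'
#' One resource per line, canonical serialization.
#'
#' @param path File path.
#' @return `fhir_read_ndjson()` returns a list of `fhir_resource` trees.
#' @export
fhir_read_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, fhir_parse)
}

#' @rdname fhir_read_ndjson
#' @param resources List of `fhir_resource` trees.
#' @export
fhir_write_ndjson <- function(resources, path) {
  writeLines(vapply(resources, fhir_serialize, character(1)), path)
  invisible(path)
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat("<fhir_resource> ", x$resourceType,
      if (!is.null(x$id)) paste0("/", x$id) else "", "\n", sep = "")
  cat(fhir_serialize(x, pretty = TRUE), "\n")
  invisible(x)
}

# Condition constructor shared across modules: every pghdflow error carries a
# machine-readable code in its class, e.g. pghd_error_duplicate-request
pghd_error <- function(code, message) {
  structure(
    class = c(paste0("pghd_error_", code), "pghd_error", "error", "condition"),
    list(message = message, call = NULL, code = code)
  )
}

# Reference token "Patient/p1" -> list(reference = "Patient/p1")
fhir_reference <- function(ref, display = NULL) {
  out <- list(reference = ref)
  if (!is.null(display)) out$display <- display
  out
}

ref_id <- function(ref) {
  if (is.list(ref)) ref <- ref$reference
  sub("^[A-Za-z]+/", "", ref %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
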