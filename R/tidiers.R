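#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a session into its answer table
#'
#' @param x A `pghd_session`.
#' @param ... Unused.
#' @return Tibble with one row per recorded answer: `linkId`, `type`,
#'   `value` (list-column).
#' @method tidy pghd_session
#' @export
tidy.pghd_session <- function(x, ...) {
  env <- x$env
  ids <- names(env$answers)
  types <- vapply(ids, function(id) {
    st <- purrr::detect(env$steps, function(s) identical(s$linkId, id))
    st$answer_type %||% "choice"
  }, character(1))
  tibble::tibble(linkId = ids, type = unname(types),
                 value = unname(env$answers))
}

#' One-row session summary
#'
#' @param x A `pghd_session`.
#' @param ... Unused.
#' @return Tibble: `mode`, `status`, `n_issued`, `n_answered`,
#'   `session_uuid`.
#' @method glance pghd_session
#' @export
glance.pghd_session <- function(x, ...) {
  tibble::tibble(mode = x$mode, status = x$env$status,
                 n_issued = length(unique(x$env$issued)),
                 n_answered = length(x$env$answers),
                 session_uuid = x$session_uuid)
}

#' Tidy an adaptive service's session table
#'
#' @param x An `adaptive_service`.
#' @param ... Unused.
#' @return Tibble with one row per administered item per session:
#'   `session`, `position`, `linkId`, `score`, and the running EAP `theta`
#'   and `se` after that item.
#' @method tidy adaptive_service
#' @export
tidy.adaptive_service <- function(x, ...) {
  sessions <- x$env$sessions
  if (length(sessions) == 0) {
    return(tibble::tibble(session = character(), position = integer(),
                          linkId = character(), score = integer(),
                          theta = double(), se = double()))
  }
  purrr::imap_dfr(sessions, function(st, uuid) {
    n <- nrow(st$administered)
    ests <- purrr::map(seq_len(n), function(k) {
      eap_estimate(st$administered[seq_len(k), , drop = FALSE], x$bank)
    })
    tibble::tibble(session = uuid, position = seq_len(n),
                   linkId = st$administered$linkId,
                   score = st$administered$score,
                   theta = vapply(ests, `[[`, 0, "theta"),
                   se = vapply(ests, `[[`, 0, "se"))
  })
}

#' One-row-per-session adaptive summary
#'
#' @param x An `adaptive_service`.
#' @param ... Unused.
#' @return Tibble: `session`, `n_items`, `theta`, `se`, `t_score`,
#'   `finished`.
#' @method glance adaptive_service
#' @export
glance.adaptive_service <- function(x, ...) {
  purrr::imap_dfr(x$env$sessions, function(st, uuid) {
    est <- eap_estimate(st$administered, x$bank)
    tibble::tibble(session = uuid, n_items = nrow(st$administered),
                   theta = est$theta, se = est$se,
                   t_score = 50 + 10 * est$theta, finished = st$finished)
  })
}

#' Plot a schedule's slot windows
#'
#' @param object A `pghd_schedule`.
#' @param as_of,report_dates Passed to [compute_slots()].
#' @param ... Unused.
#' @return A ggplot: one horizontal segment per slot, colored by
#'   fulfilment.
#' @method autoplot pghd_schedule
#' @export
autoplot.pghd_schedule <- function(object, as_of = Sys.Date(),
                                   report_dates = NULL, ...) {
  slots <- compute_slots(object, as_of = as_of, report_dates = report_dates)
  ggplot2::ggplot(slots, ggplot2::aes(y = factor(.data$index))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = factor(.data$index),
                                       color = .data$fulfilled),
                          linewidth = 3) +
    ggplot2::labs(x = NULL, y = "slot", color = "fulfilled",
                  title = paste0(object$kind, " schedule")) +
    ggplot2::theme_minimal()
}

#' Plot the measurement-precision trajectory of adaptive sessions
#'
#' @param object An `adaptive_service`.
#' @param ... Unused.
#' @return A ggplot of the running standard error against items
#'   administered, one line per session.
#' @method autoplot adaptive_service
#' @export
autoplot.adaptive_service <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$se,
                                  group = .data$session)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "items administered", y = "posterior SE",
                  title = "Adaptive session precision") +
    ggplot2::theme_minimal()
}
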