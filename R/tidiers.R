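#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted Cox driver model
#'
#' @param x A `driver_cox` object.
#' @param ... Unused.
#' @return One row per model term: `term`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
tidy.driver_cox <- function(x, ...) {
  x$terms
}

#' Model-level summary of a fitted Cox driver model
#'
#' @param x A `driver_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `model_type`, `n`, `n_events`, `flagged`, `note`,
#'   and `interaction_p` for interaction models.
#' @export
glance.driver_cox <- function(x, ...) {
  out <- tibble(
    model_type = x$model_type,
    n = x$n,
    n_events = x$n_events,
    flagged = x$flagged,
    note = x$note %||% NA_character_
  )
  if (!is.null(x$interaction_p)) out$interaction_p <- x$interaction_p
  out
}

#' Tidy a Kaplan-Meier MATH-quartile comparison
#'
#' @param x A `km_math` object.
#' @param ... Unused.
#' @return The product-limit curve as a tibble: `group`, `time`, `n_risk`,
#'   `n_event`, `estimate`.
#' @export
tidy.km_math <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(
    group = sub("^group=", "", as.character(s$strata)),
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    estimate = s$surv
  )
}

#' @rdname tidy.km_math
#' @export
glance.km_math <- function(x, ...) {
  tibble(
    n = nrow(x$groups),
    logrank_p = x$logrank_p,
    lower_quartile = unname(x$quartiles[1]),
    upper_quartile = unname(x$quartiles[2])
  )
}
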