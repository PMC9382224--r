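#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a feeding-site selection fit
#'
#' @param x A `feeding_model_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy feeding_model_fit
#' @export
tidy.feeding_model_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "ftle"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$se_intercept, x$se_slope),
         statistic = c(x$intercept / x$se_intercept, x$slope / x$se_slope),
         p.value = c(NA_real_, x$p_slope))
}

#' @rdname tidy.feeding_model_fit
#' @method glance feeding_model_fit
#' @export
glance.feeding_model_fit <- function(x, ...) {
  tibble(n_dives = x$n_dives, n_individuals = x$n_individuals,
         phi = x$phi, random = x$random, correlation = x$correlation)
}

#' Tidy a fitted transition model
#'
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return One row per (from, to, term) coefficient with estimate and
#'   standard error; self-transitions (the reference category) are omitted.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  S <- x$n_states
  rows <- list()
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    rows[[length(rows) + 1]] <- tibble(
      from = x$labels[i], to = x$labels[j],
      term = c("(Intercept)", "ftle"),
      estimate = x$beta[i, j, ], std.error = x$se[i, j, ])
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.transition_model
#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  tibble(n_states = x$n_states, n_transitions = x$n_transitions)
}
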