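# broom-style tidiers for fitted objects.

#' Tidy a fitted observer model
#'
#' @param x A `heading_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`.
#' @method tidy heading_fit
#' @export
tidy.heading_fit <- function(x, ...) {
  nm <- model_free_params(x$model_id)
  tibble(term = nm, estimate = unlist(x$map_params[nm], use.names = FALSE))
}

#' Glance at a fitted observer model
#'
#' @param x A `heading_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model_id`, `observer`, `k`,
#'   `log_likelihood`, `log_posterior`, `aic`, `r_squared`, `converged`.
#' @export
glance.heading_fit <- function(x, ...) {
  tibble(model_id = x$model_id, observer = x$observer, k = x$k,
         log_likelihood = x$log_likelihood, log_posterior = x$log_posterior,
         aic = x$aic,
         r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
         converged = x$converged)
}

#' Tidy a model-comparison table
#'
#' @param x A `heading_compare` from [compare_models()].
#' @param ... Unused.
#' @return The comparison tibble, one row per non-reference model.
#' @method tidy heading_compare
#' @export
tidy.heading_compare <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a regression decomposition
#'
#' @param x A `heading_regression`.
#' @param ... Unused.
#' @return Per-observer coefficient tibble.
#' @method tidy heading_regression
#' @export
tidy.heading_regression <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.heading_regression
#' @method glance heading_regression
#' @export
glance.heading_regression <- function(x, ...) {
  x$group_tests
}
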