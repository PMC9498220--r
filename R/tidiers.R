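#' Tidy a scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`intercept`, `slope`).
#' @method tidy scaling_fit
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `estimator`, `slope`, `intercept`,
#'   `r_squared`, `n_points`, `n_dropped`, `space`.
#' @method glance scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(estimator = x$estimator, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_points = x$n_points,
         n_dropped = x$n_dropped, space = x$space)
}

#' Tidy an estimator-exponent association
#'
#' @param x An `alpha_assoc` from [fit_alpha_association()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy alpha_assoc
#' @export
tidy.alpha_assoc <- function(x, ...) {
  tibble(estimator = x$estimator, alpha_range = x$alpha_range,
         condition = x$condition, r_squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, n_points = x$n_points)
}

#' @rdname tidy.alpha_assoc
#' @method glance alpha_assoc
#' @export
glance.alpha_assoc <- function(x, ...) tidy(x)

#' Long-format records of a simulation run
#'
#' @param x An `rqa_sim` from [run_simulation()].
#' @param ... Unused.
#' @return The records tibble (`true_alpha`, `condition`, `rep`,
#'   `estimator`, `estimate`).
#' @method tidy rqa_sim
#' @export
tidy.rqa_sim <- function(x, ...) x$records

#' One-row summary of a simulation run
#'
#' @param x An `rqa_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the run dimensions and failure count.
#' @method glance rqa_sim
#' @export
glance.rqa_sim <- function(x, ...) {
  tibble(n_alphas = length(x$config$alpha_grid), reps = x$config$reps,
         n_conditions = length(x$config$conditions),
         series_length = x$config$n, n_records = nrow(x$records),
         n_failures = nrow(x$failures), seed = x$config$seed)
}
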