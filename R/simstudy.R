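#' Configuration of the Monte-Carlo estimator comparison
#'
#' Full provenance for one simulation run: the synthetic-data design (alpha
#' grid, repetitions, length, conditions, noise level, master seed) and the
#' analysis parameters (recurrence, bin-scaling and DFA configurations).
#' The defaults are the reference study design: 7 exponents from -1 to 2 in
#' steps of 0.5, 100 series of 1026 samples each per exponent, idealized and
#' noisy (SNR 2:1) conditions.
#'
#' @param alpha_grid Numeric vector of true spectral exponents.
#' @param reps Realizations per exponent and condition.
#' @param n Series length.
#' @param conditions Subset of `c("ideal", "noisy")`.
#' @param noise_sd_fraction Noise SD as a fraction of signal SD for the
#'   noisy condition.
#' @param seed Master seed; every series seed derives from it.
#' @param rqa,bins,dfa Parameter objects ([rqa_params()],
#'   [bin_scaling_config()], [dfa_config()]).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(alpha_grid = seq(-1, 2, by = 0.5), reps = 100,
                       n = 1026, conditions = c("ideal", "noisy"),
                       noise_sd_fraction = 0.5, seed = 1,
                       rqa = rqa_params(), bins = bin_scaling_config(),
                       dfa = NULL) {
  conditions <- match.arg(conditions, c("ideal", "noisy"), several.ok = TRUE)
  dfa <- dfa %||% dfa_config(min_bin = 10, max_bin = min(510, n %/% 2))
  structure(list(alpha_grid = as.numeric(alpha_grid), reps = as.integer(reps),
                 n = as.integer(n), conditions = conditions,
                 noise_sd_fraction = as.numeric(noise_sd_fraction),
                 seed = as.integer(seed), rqa = rqa, bins = bins, dfa = dfa),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d alphas (%g..%g) x %d reps x {%s}, n = %d, noise SD fraction = %g, seed = %d\n",
              length(x$alpha_grid), min(x$alpha_grid), max(x$alpha_grid),
              x$reps, paste(x$conditions, collapse = ", "), x$n,
              x$noise_sd_fraction, x$seed))
  invisible(x)
}

#' Run the Monte-Carlo estimator comparison
#'
#' Generates the full synthetic dataset of the configuration and analyzes
#' every series with all six estimators ([estimate_all()]). Per-series
#' estimator failures (degenerate inputs) are recorded with their reason and
#' excluded from the long-format records rather than aborting the run. The
#' run is fully reproducible from the master seed.
#'
#' @param config A [sim_config()].
#' @param quiet Suppress per-exponent progress messages?
#'
#' @return An object of class `rqa_sim`: a list with `records` (tibble:
#'   `true_alpha`, `condition`, `rep`, `estimator`, `estimate`), `failures`
#'   (tibble: series identifiers, estimator, reason) and `config`.
#' @export
#' @examples
#' sim <- run_simulation(sim_config(alpha_grid = c(0, 1), reps = 2, n = 128,
#'                                  conditions = "ideal",
#'                                  dfa = dfa_config(10, 60, 8)),
#'                       quiet = TRUE)
#' nrow(sim$records) # 2 x 2 x 1 x 6
run_simulation <- function(config = sim_config(), quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(ai = seq_along(config$alpha_grid),
                             rep = seq_len(config$reps))
  records <- vector("list", nrow(grid) * length(config$conditions))
  failures <- list()
  k <- 0L
  for (ai in seq_along(config$alpha_grid)) {
    alpha <- config$alpha_grid[ai]
    if (!quiet) inform(sprintf("alpha = %g (%d reps x %d conditions)",
                               alpha, config$reps, length(config$conditions)))
    for (rep in seq_len(config$reps)) {
      sig <- generate_power_noise(
        noise_spec(alpha, config$n, mix_seed(config$seed, 1L, ai, rep)))
      for (cond in config$conditions) {
        x <- if (cond == "noisy") {
          add_observation_noise(sig, config$noise_sd_fraction,
                                seed = mix_seed(config$seed, 2L, ai, rep))
        } else {
          sig
        }
        est <- suppressWarnings(
          estimate_all(x, params = config$rqa, cfg = config$bins,
                       dfa_cfg = config$dfa))
        long <- tidyr::pivot_longer(est, dplyr::everything(),
                                    names_to = "estimator",
                                    values_to = "estimate")
        fl <- attr(est, "failures")
        if (length(fl) > 0) {
          failures[[length(failures) + 1L]] <-
            tibble(true_alpha = alpha, condition = cond, rep = rep,
                   estimator = names(fl), reason = unname(fl))
          long <- long[!is.na(long$estimate), ]
        }
        k <- k + 1L
        records[[k]] <- dplyr::bind_cols(
          tibble(true_alpha = alpha, condition = cond, rep = rep), long)
      }
    }
  }
  structure(list(records = dplyr::bind_rows(records),
                 failures = dplyr::bind_rows(failures),
                 config = config),
            class = "rqa_sim")
}

#' @export
print.rqa_sim <- function(x, ...) {
  cat(sprintf("<rqa_sim> %d records (%d estimator failures)\n",
              nrow(x$records), nrow(x$failures)))
  print(x$config)
  invisible(x)
}

range_filter <- function(alpha_range) {
  switch(alpha_range,
         persistent = function(a) a >= 0,
         antipersistent = function(a) a <= 0,
         full = function(a) rep(TRUE, length(a)),
         stop_rqascale("`alpha_range` must be 'persistent', 'antipersistent' or 'full'.",
                       "invalid_spec"))
}

#' Association between an estimator and the true exponent
#'
#' OLS regression of the per-series estimates on the true spectral exponent,
#' pooled over repetitions, within one condition and one exponent range.
#' Following the reference design, the boundary exponent 0 belongs to both
#' the persistent (`alpha >= 0`) and antipersistent (`alpha <= 0`) ranges.
#' The reported `r_squared` is the squared Pearson correlation of the fit.
#'
#' @param result An `rqa_sim` from [run_simulation()], or its `records`
#'   tibble.
#' @param estimator One of `"sd_rec_slope"`, `"lam"`, `"diag_slope"`,
#'   `"wk_slope"`, `"diag_ratio"`, `"dfa_h"`.
#' @param alpha_range `"persistent"`, `"antipersistent"` or `"full"`.
#' @param condition `"ideal"` or `"noisy"`.
#'
#' @return An object of class `alpha_assoc` with fields `estimator`,
#'   `alpha_range`, `condition`, `r_squared`, `slope`, `intercept`,
#'   `n_points`.
#' @export
fit_alpha_association <- function(result, estimator,
                                  alpha_range = c("full", "persistent",
                                                  "antipersistent"),
                                  condition = "ideal") {
  records <- if (inherits(result, "rqa_sim")) result$records else result
  alpha_range <- match.arg(alpha_range)
  keep <- range_filter(alpha_range)
  d <- records[records$estimator == estimator &
                 records$condition == condition &
                 keep(records$true_alpha) & is.finite(records$estimate), ]
  if (length(unique(d$true_alpha)) < 3) {
    stop_rqascale("Need at least 3 distinct alpha levels in the range.",
                  "insufficient_data")
  }
  fit <- new_scaling_fit(d$true_alpha, d$estimate, "linear",
                         estimator = estimator)
  structure(list(estimator = estimator, alpha_range = alpha_range,
                 condition = condition, r_squared = fit$r_squared,
                 slope = fit$slope, intercept = fit$intercept,
                 n_points = nrow(d)),
            class = "alpha_assoc")
}

#' @export
print.alpha_assoc <- function(x, ...) {
  cat(sprintf("<alpha_assoc> %s ~ alpha (%s, %s): R^2 = %.3f, slope = %.4f (n = %d)\n",
              x$estimator, x$alpha_range, x$condition, x$r_squared, x$slope,
              x$n_points))
  invisible(x)
}

#' Estimator-by-range-by-condition summary grid
#'
#' Fits [fit_alpha_association()] for every estimator in the records over
#' the persistent and antipersistent ranges and every condition present,
#' yielding the study's headline comparison grid. Cells where more than 5%
#' of series failed for that estimator and condition are flagged.
#'
#' @param result An `rqa_sim` from [run_simulation()].
#' @param alpha_ranges Ranges to tabulate (default persistent and
#'   antipersistent).
#'
#' @return A tibble with one row per estimator x range x condition:
#'   `estimator`, `alpha_range`, `condition`, `r_squared`, `slope`,
#'   `n_points`, `flagged`.
#' @export
summarize_table <- function(result,
                            alpha_ranges = c("persistent", "antipersistent")) {
  stopifnot(inherits(result, "rqa_sim"))
  records <- result$records
  conds <- unique(records$condition)
  ests <- unique(records$estimator)
  n_series <- result$config$reps * length(result$config$alpha_grid)
  grid <- tidyr::expand_grid(estimator = ests, alpha_range = alpha_ranges,
                             condition = conds)
  purrr::pmap_dfr(grid, function(estimator, alpha_range, condition) {
    a <- fit_alpha_association(result, estimator, alpha_range, condition)
    nfail <- if (nrow(result$failures) == 0) 0L else {
      sum(result$failures$estimator == estimator &
            result$failures$condition == condition)
    }
    tibble(estimator = estimator, alpha_range = alpha_range,
           condition = condition, r_squared = a$r_squared, slope = a$slope,
           n_points = a$n_points, flagged = nfail > 0.05 * n_series)
  })
}
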