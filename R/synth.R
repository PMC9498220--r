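#' Specification of a synthetic 1/f^alpha series
#'
#' Bundles the parameters of one synthetic colored-noise realization: the
#' spectral exponent `alpha` of the target power law (power density
#' proportional to `f^-alpha`), the series length, the RNG seed, and the
#' standard deviation of additive Gaussian observation noise expressed as a
#' fraction of the signal SD (`0` = idealized signal, `0.5` = a 2:1
#' signal-to-noise amplitude ratio).
#'
#' @param alpha Spectral exponent of the `1/f^alpha` target spectrum.
#'   `alpha = 0` is white noise, `alpha = 1` pink noise, `alpha = 2`
#'   Brownian-like noise; negative values give antipersistent (blue-ish)
#'   noise.
#' @param n Series length in samples (at least 64).
#' @param seed Integer RNG seed, or `NULL` to draw from the current RNG
#'   state.
#' @param noise_sd_fraction SD of additive Gaussian observation noise as a
#'   fraction of the signal SD; non-negative.
#'
#' @return An object of class `noise_spec` (a named list).
#' @seealso [generate_power_noise()], [make_dataset()]
#' @export
#' @examples
#' noise_spec(alpha = 1, n = 256, seed = 1)
noise_spec <- function(alpha, n = 1026L, seed = NULL, noise_sd_fraction = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha)) {
    stop_rqascale("`alpha` must be a single finite number.", "invalid_spec")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 64) {
    stop_rqascale("`n` must be a single integer >= 64.", "invalid_spec")
  }
  if (!is.numeric(noise_sd_fraction) || noise_sd_fraction < 0) {
    stop_rqascale("`noise_sd_fraction` must be >= 0.", "invalid_spec")
  }
  structure(
    list(alpha = as.numeric(alpha), n = as.integer(n),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         noise_sd_fraction = as.numeric(noise_sd_fraction)),
    class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> alpha = %g, n = %d, seed = %s, noise SD fraction = %g\n",
              x$alpha, x$n, if (is.null(x$seed)) "NULL" else x$seed,
              x$noise_sd_fraction))
  invisible(x)
}

#' Generate a 1/f^alpha colored-noise series by spectral synthesis
#'
#' Draws one realization of a power-law noise process whose expected
#' periodogram is proportional to `f^-alpha`. The construction is the
#' standard frequency-domain one: positive-frequency Fourier amplitudes are
#' set to `k^(-alpha/2)` with i.i.d. uniform random phases, the DC component
#' is zero, the Nyquist bin is real-valued, Hermitian symmetry is imposed,
#' and the series is the real part of the inverse FFT. Only the random
#' phases (and the sign of the Nyquist bin) are stochastic, so realizations
#' have essentially fixed spectral content.
#'
#' The amplitude scale is arbitrary: downstream recurrence analysis z-scores
#' the series, so no renormalization is applied here.
#'
#' @param spec A [noise_spec()]. Its `noise_sd_fraction` is ignored here;
#'   use [add_observation_noise()] to contaminate the signal.
#'
#' @return A numeric vector of length `spec$n`.
#' @export
#' @examples
#' x <- generate_power_noise(noise_spec(alpha = 2, n = 256, seed = 7))
#' stats::cor(x[-1], x[-256]) # strongly persistent: lag-1 autocorrelation near 1
generate_power_noise <- function(spec) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, as.list(spec))
  n <- spec$n
  half <- n %/% 2
  with_seed_maybe(spec$seed, {
    k <- seq_len(half - 1L)
    amp <- k^(-spec$alpha / 2)
    phase <- runif(half - 1L, 0, 2 * pi)
    X <- complex(length.out = n)
    X[1L + k] <- amp * exp(1i * phase)
    if (n %% 2 == 0) {
      # real-valued Nyquist bin, random sign via a random phase projection
      X[1L + half] <- half^(-spec$alpha / 2) * cos(runif(1, 0, 2 * pi))
    } else {
      kh <- half # odd n: bins 1..half are all paired
      X[1L + kh] <- kh^(-spec$alpha / 2) * exp(1i * runif(1, 0, 2 * pi))
    }
    X[n + 1L - k] <- Conj(X[1L + k])
    if (n %% 2 == 1) X[n + 1L - half] <- Conj(X[1L + half])
    Re(fft(X, inverse = TRUE)) / n
  })
}

#' Add Gaussian observation noise scaled to the signal SD
#'
#' Contaminates a series with zero-mean i.i.d. Gaussian noise whose SD is
#' `noise_sd_fraction` times the SD of the input, so
#' `noise_sd_fraction = 0.5` yields a 2:1 signal-to-noise amplitude ratio
#' and inflates the variance by a factor of 1.25 in expectation.
#'
#' @param series Numeric vector (or single-numeric-column data frame).
#' @param noise_sd_fraction Noise SD as a fraction of `sd(series)`;
#'   non-negative. `0` returns the input unchanged.
#' @param seed Optional integer seed for the noise draw.
#'
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' x <- generate_power_noise(noise_spec(alpha = 0, n = 128, seed = 1))
#' y <- add_observation_noise(x, 0.5, seed = 2)
#' stats::var(y) / stats::var(x) # about 1.25
add_observation_noise <- function(series, noise_sd_fraction, seed = NULL) {
  x <- check_series(series)
  if (!is.numeric(noise_sd_fraction) || length(noise_sd_fraction) != 1 ||
      !is.finite(noise_sd_fraction) || noise_sd_fraction < 0) {
    stop_rqascale("`noise_sd_fraction` must be a single number >= 0.",
                  "invalid_spec")
  }
  if (noise_sd_fraction == 0) return(x)
  with_seed_maybe(seed, x + rnorm(length(x), 0, noise_sd_fraction * sd(x)))
}

#' Standardize a series to zero mean and unit SD
#'
#' @param series Numeric vector (or single-numeric-column data frame) with
#'   positive SD.
#'
#' @return Numeric vector with mean 0 and SD 1.
#' @export
#' @examples
#' zscore_series(c(1, 2, 3))
zscore_series <- function(series) {
  x <- check_series(series)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_rqascale("Cannot z-score a constant series (SD = 0).",
                  "degenerate_series")
  }
  (x - mean(x)) / s
}

#' Generate the full grid of synthetic study series
#'
#' Builds the Monte-Carlo dataset of the simulation design: `reps`
#' realizations for every spectral exponent in `alpha_grid`, each under an
#' idealized and/or a noisy observation condition. The noisy series is the
#' idealized realization of the same `(alpha, rep)` cell plus Gaussian noise
#' with SD equal to `noise_sd_fraction` of the signal SD, so the two
#' conditions are paired. Per-series seeds are derived deterministically
#' from the master seed, the grid position, the repetition index and the
#' condition, so any single series can be regenerated in isolation.
#'
#' @param alpha_grid Numeric vector of spectral exponents. The default grid
#'   spans antipersistent to Brownian-like noise in steps of 0.5.
#' @param reps Number of realizations per exponent and condition.
#' @param n Series length in samples.
#' @param conditions Character subset of `c("ideal", "noisy")`.
#' @param noise_sd_fraction Noise SD fraction for the noisy condition.
#' @param seed Master integer seed.
#'
#' @return A tibble with one row per series: `true_alpha`, `condition`,
#'   `rep`, `seed` (the derived signal seed) and a `series` list-column of
#'   numeric vectors.
#' @export
#' @examples
#' d <- make_dataset(alpha_grid = c(0, 1), reps = 2, n = 128, seed = 1)
#' nrow(d) # 2 alphas x 2 reps x 2 conditions
make_dataset <- function(alpha_grid = seq(-1, 2, by = 0.5), reps = 100,
                         n = 1026, conditions = c("ideal", "noisy"),
                         noise_sd_fraction = 0.5, seed = 1) {
  if (length(alpha_grid) == 0) {
    stop_rqascale("`alpha_grid` must not be empty.", "invalid_spec")
  }
  if (!is.numeric(reps) || reps < 1) {
    stop_rqascale("`reps` must be >= 1.", "invalid_spec")
  }
  conditions <- match.arg(conditions, c("ideal", "noisy"), several.ok = TRUE)
  grid <- tidyr::expand_grid(
    ai = seq_along(alpha_grid), rep = seq_len(as.integer(reps)),
    condition = conditions)
  rows <- purrr::pmap(grid, function(ai, rep, condition) {
    signal_seed <- mix_seed(seed, 1L, ai, rep)
    sig <- generate_power_noise(noise_spec(alpha_grid[ai], n, signal_seed))
    x <- if (condition == "noisy") {
      add_observation_noise(sig, noise_sd_fraction,
                            seed = mix_seed(seed, 2L, ai, rep))
    } else {
      sig
    }
    tibble(true_alpha = alpha_grid[ai], condition = condition, rep = rep,
           seed = signal_seed, series = list(x))
  })
  dplyr::bind_rows(rows)
}
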