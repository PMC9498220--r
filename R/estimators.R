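#' Configuration for bin-wise recurrence-rate scaling (approach 1)
#'
#' @param bin_sizes Strictly increasing bin side lengths, all at least 2;
#'   powers of two by convention. The default 2, 4, ..., 256 is the largest
#'   dyadic range that keeps at least 16 complete bins in a plot of around
#'   1000 samples.
#' @param min_bins_per_size Minimum number of complete bins required for a
#'   size to enter the fit; sizes tiling fewer bins are dropped (the SD over
#'   very few bins is unstable).
#' @param truncate If `TRUE`, truncate the plot to the largest multiple of
#'   the biggest bin size before tiling instead of discarding incomplete
#'   edge bins per size.
#'
#' @return An object of class `bin_scaling_config`.
#' @export
bin_scaling_config <- function(bin_sizes = 2^(1:8), min_bins_per_size = 4,
                               truncate = FALSE) {
  if (any(bin_sizes < 2) || is.unsorted(bin_sizes, strictly = TRUE)) {
    stop_rqascale("`bin_sizes` must be strictly increasing and >= 2.",
                  "invalid_spec")
  }
  structure(list(bin_sizes = as.integer(bin_sizes),
                 min_bins_per_size = as.integer(min_bins_per_size),
                 truncate = isTRUE(truncate)),
            class = "bin_scaling_config")
}

## scaling_fit: common container for the OLS fits used by every estimator
new_scaling_fit <- function(x, y, space = c("log-log", "linear"),
                            estimator = NA_character_, n_dropped = 0L) {
  space <- match.arg(space)
  fit <- lm(y ~ x)
  res <- stats::residuals(fit)
  sst <- sum((y - mean(y))^2)
  # a zero-variance response carries no association: report R^2 = 0
  r2 <- if (sst < .Machine$double.eps^0.5) {
    0
  } else {
    max(0, min(1, 1 - sum(res^2) / sst))
  }
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = length(x), space = space,
         estimator = estimator, n_dropped = as.integer(n_dropped),
         data = tibble(x = x, y = y)),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit: %s> slope = %.4f, intercept = %.4f, R^2 = %.4f (%d points, %s space)\n",
              x$estimator, x$slope, x$intercept, x$r_squared, x$n_points,
              x$space))
  if (x$n_dropped > 0) cat(sprintf("  %d zero/invalid points dropped\n", x$n_dropped))
  invisible(x)
}

#' Approach 1: scaling of the SD of %REC across bin sizes
#'
#' Tiles the recurrence plot with non-overlapping `b x b` bins (anchored at
#' the top-left corner, incomplete edge bins discarded) for each bin size
#' `b`, computes the recurrence rate per bin and its SD across bins, and
#' fits an OLS line to `log(SD)` versus `log(b)`. For an i.i.d. random plot
#' the SD of a proportion over `b^2` cells scales as `1/b` (slope -1);
#' clustered recurrences from persistent signals decay more slowly (slope
#' closer to 0), so the slope tracks the scaling exponent for persistent
#' series.
#'
#' Bin sizes with zero SD are dropped with a warning; if fewer than three
#' sizes remain the fit is degenerate and an error of class
#' `rqascale_degenerate_scaling` is raised.
#'
#' @param rp A [recurrence_plot()] or square binary matrix.
#' @param cfg A [bin_scaling_config()].
#'
#' @return A `scaling_fit` with the slope as the scaling estimate.
#' @export
bin_sd_scaling <- function(rp, cfg = bin_scaling_config()) {
  m <- as_rp_matrix(rp)
  stopifnot(inherits(cfg, "bin_scaling_config"))
  n <- nrow(m)
  if (cfg$truncate) {
    n_t <- (n %/% max(cfg$bin_sizes)) * max(cfg$bin_sizes)
    if (n_t >= 2) {
      m <- m[seq_len(n_t), seq_len(n_t)]
      n <- n_t
    }
  }
  sizes <- cfg$bin_sizes[(n %/% cfg$bin_sizes) >= cfg$min_bins_per_size]
  if (length(sizes) < 3) {
    stop_rqascale("Fewer than 3 usable bin sizes for this plot.",
                  "insufficient_data")
  }
  ## summed-area table: any b x b block sum in O(1) afterwards
  sat <- apply(m, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  P <- matrix(0, n + 1, n + 1)
  P[-1, -1] <- sat
  sds <- vapply(sizes, function(b) {
    k <- n %/% b
    e <- seq.int(b, k * b, by = b)       # block end indices
    s <- e - b + 1L                      # block start indices
    sums <- P[e + 1L, e + 1L] - P[s, e + 1L] - P[e + 1L, s] + P[s, s]
    sd(sums / b^2)
  }, numeric(1))
  ok <- sds > 0
  if (sum(ok) < 3) {
    stop_rqascale("SD of %REC is zero at (almost) every bin size; no scaling to fit.",
                  "degenerate_scaling")
  }
  if (any(!ok)) {
    warn(sprintf("Dropping %d bin size(s) with zero SD before fitting.",
                 sum(!ok)))
  }
  new_scaling_fit(log(sizes[ok]), log(sds[ok]), "log-log",
                  estimator = "sd_rec_slope", n_dropped = sum(!ok))
}

subset_profile <- function(profile, lag_max) {
  stopifnot(is.data.frame(profile), all(c("lag", "rec_rate") %in% names(profile)))
  if (!is.null(lag_max)) profile <- profile[profile$lag <= lag_max, ]
  profile
}

#' Approach 3: log-log slope of the diagonal recurrence profile
#'
#' Fits an OLS line to `log(rec_rate)` versus `log(lag)` over the profile
#' lags with nonzero rate (zero-rate lags are dropped and counted). The
#' diagonal profile plays the role of an autocorrelation function, so a
#' more negative slope indicates dominance of low frequencies, i.e. a more
#' persistent signal; white noise gives a flat profile and slope 0.
#'
#' @param profile A [diagonal_profile()] tibble.
#' @param lag_max Optional upper lag for the fit window. Scaling information
#'   concentrates at small lags before the profile flattens into the
#'   background recurrence rate; [estimate_all()] uses `floor(N / 16)`.
#'
#' @return A `scaling_fit`; the slope is the scaling estimate.
#' @export
diag_profile_scaling <- function(profile, lag_max = NULL) {
  profile <- subset_profile(profile, lag_max)
  ok <- profile$rec_rate > 0
  if (sum(ok) < 3) {
    stop_rqascale("Need at least 3 lags with nonzero recurrence rate.",
                  "insufficient_data")
  }
  new_scaling_fit(log(profile$lag[ok]), log(profile$rec_rate[ok]), "log-log",
                  estimator = "diag_slope", n_dropped = sum(!ok))
}

#' Wiener-Khinchin variant: spectral slope of the diagonal profile
#'
#' Treats the diagonal recurrence profile as an autocorrelation-like
#' sequence and applies the Wiener-Khinchin correspondence: the discrete
#' Fourier power spectrum of the (mean-removed) profile estimates the power
#' spectrum of the underlying signal, and an OLS line is fitted to
#' `log(power)` versus `log(frequency index)` over the positive-frequency
#' bins (the zero-frequency bin is excluded).
#'
#' @param profile A [diagonal_profile()] tibble of at least 8 lags.
#' @param lag_max Optional truncation of the profile before the transform;
#'   [estimate_all()] uses `floor(N / 32)`, keeping the small-lag segment
#'   that carries the autocorrelation decay.
#'
#' @return A `scaling_fit`; the slope is the scaling estimate.
#' @export
wk_spectrum_scaling <- function(profile, lag_max = NULL) {
  profile <- subset_profile(profile, lag_max)
  p <- profile$rec_rate
  if (length(p) < 8) {
    stop_rqascale("Profile must have at least 8 lags.", "insufficient_data")
  }
  p <- p - mean(p)
  np <- length(p)
  power <- Mod(fft(p))^2 / np
  half <- np %/% 2
  f <- seq_len(half)
  pw <- power[1L + f]
  ok <- pw > .Machine$double.eps
  if (sum(ok) < 3) {
    stop_rqascale("Spectrum is (numerically) zero after mean removal; constant profile?",
                  "degenerate_spectrum")
  }
  new_scaling_fit(log(f[ok]), log(pw[ok]), "log-log",
                  estimator = "wk_slope", n_dropped = sum(!ok))
}

#' Approach 4: mean ratio of consecutive diagonal recurrence rates
#'
#' For each adjacent lag pair `(d, d + 1)` with both rates nonzero, forms a
#' ratio of the two recurrence rates and returns the mean over pairs.
#' Antipersistent signals oscillate near the Nyquist frequency, which
#' depresses the odd-lag diagonals relative to their even neighbors, so the
#' ratio rises above 1 as the exponent decreases below 0; smooth persistent
#' profiles give ratios near 1.
#'
#' With `orientation = "directed"` (default) each pair contributes
#' `rate(d + 1) / rate(d)`, which preserves the sign of the first-lag
#' depression, is centered at 1 under pure sampling noise, and converges to
#' 1 for all non-antipersistent signals. `orientation = "fold"` contributes
#' `max / min >= 1`, so that the statistic is 1 exactly when the profile is
#' constant over the window and grows with alternation of either sign; its
#' expectation sits above 1 even for featureless profiles, because folding
#' rectifies the sampling noise.
#'
#' @param profile A [diagonal_profile()] tibble with at least 2 lags.
#' @param lag_max Optional upper lag of the pair window. The alternation
#'   signature of antipersistence decays quadratically with lag, so only
#'   the first few pairs are informative; [estimate_all()] uses lags 1-6.
#' @param orientation `"directed"` or `"fold"`; see Details.
#'
#' @return The mean ratio (numeric scalar) with attributes `n_pairs` and
#'   `n_dropped` (pairs skipped for a zero member).
#' @export
consecutive_diag_ratio <- function(profile, lag_max = NULL,
                                   orientation = c("directed", "fold")) {
  orientation <- match.arg(orientation)
  profile <- subset_profile(profile, lag_max)
  if (nrow(profile) < 2) {
    stop_rqascale("Profile must have at least 2 lags.", "insufficient_data")
  }
  a <- profile$rec_rate[-nrow(profile)]
  b <- profile$rec_rate[-1]
  ok <- a > 0 & b > 0
  if (!any(ok)) {
    stop_rqascale("No adjacent lag pair with both rates nonzero.",
                  "insufficient_data")
  }
  r <- if (orientation == "fold") {
    mean(pmax(a[ok], b[ok]) / pmin(a[ok], b[ok]))
  } else {
    mean(b[ok] / a[ok])
  }
  structure(r, n_pairs = sum(ok), n_dropped = sum(!ok))
}

#' Run every scaling estimator on one series
#'
#' Builds the recurrence plot and diagonal profile once and applies all six
#' estimators: the bin-SD slope (approach 1), laminarity (approach 2), the
#' diagonal-profile slope (approach 3), the Wiener-Khinchin spectral slope,
#' the consecutive-diagonal ratio (approach 4), and the DFA Hurst exponent
#' benchmark. Estimators that fail on degenerate input are reported as `NA`
#' with the reason recorded, not as an error.
#'
#' The estimator-specific lag windows default to `floor(n / 16)` for the
#' profile slope, `floor(n / 32)` for the spectral variant, and lag 6 for
#' the ratio; see the individual estimator pages for the rationale.
#'
#' @param series Numeric vector of at least 64 samples.
#' @param params An [rqa_params()].
#' @param cfg A [bin_scaling_config()].
#' @param dfa_cfg A [dfa_config()]; defaults to windows between 10 and
#'   `floor(n / 2)` samples.
#' @param diag_lag_max,wk_lag_max,ratio_lag_max Optional overrides of the
#'   per-estimator lag windows.
#'
#' @return A one-row tibble with columns `sd_rec_slope`, `lam`,
#'   `diag_slope`, `wk_slope`, `diag_ratio`, `dfa_h`, carrying a `failures`
#'   attribute (named character vector of failure reasons, empty when all
#'   succeeded).
#' @export
#' @examples
#' x <- generate_power_noise(noise_spec(alpha = 1, n = 256, seed = 3))
#' estimate_all(x)
estimate_all <- function(series, params = rqa_params(),
                         cfg = bin_scaling_config(), dfa_cfg = NULL,
                         diag_lag_max = NULL, wk_lag_max = NULL,
                         ratio_lag_max = NULL) {
  x <- check_series(series, n_min = 64)
  n <- length(x)
  dfa_cfg <- dfa_cfg %||% dfa_config(min_bin = 10, max_bin = min(510, n %/% 2))
  diag_lag_max <- diag_lag_max %||% max(8L, n %/% 16L)
  wk_lag_max <- wk_lag_max %||% max(16L, n %/% 32L)
  ratio_lag_max <- ratio_lag_max %||% 6L
  rp <- recurrence_plot(x, params)
  profile <- diagonal_profile(rp)
  failures <- character(0)
  run <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  out <- tibble(
    sd_rec_slope = run("sd_rec_slope", function() bin_sd_scaling(rp, cfg)$slope),
    lam = run("lam", function() laminarity(rp)),
    diag_slope = run("diag_slope",
                     function() diag_profile_scaling(profile, diag_lag_max)$slope),
    wk_slope = run("wk_slope",
                   function() wk_spectrum_scaling(profile, wk_lag_max)$slope),
    diag_ratio = run("diag_ratio",
                     function() as.numeric(consecutive_diag_ratio(profile, ratio_lag_max))),
    dfa_h = run("dfa_h", function() dfa_hurst(x, dfa_cfg)$slope))
  attr(out, "failures") <- failures
  out
}
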