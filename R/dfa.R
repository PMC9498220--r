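#' Detrended fluctuation analysis configuration
#'
#' @param min_bin Smallest window length in samples (default 10).
#' @param max_bin Largest window length in samples (default 510).
#' @param n_scales Number of window sizes, log-spaced between `min_bin` and
#'   `max_bin` and rounded to unique integers (default 15).
#' @param detrend_order Polynomial order of the per-window detrending
#'   (default 1, linear).
#' @param both_ends If `TRUE`, windows are tiled from both ends of the
#'   profile and the fluctuation pools both passes; by default windows are
#'   tiled from the start only and the trailing remainder is discarded.
#'
#' @return An object of class `dfa_config`.
#' @export
dfa_config <- function(min_bin = 10, max_bin = 510, n_scales = 15,
                       detrend_order = 1, both_ends = FALSE) {
  if (min_bin < 4 || min_bin >= max_bin) {
    stop_rqascale("Need 4 <= min_bin < max_bin.", "invalid_spec")
  }
  if (n_scales < 4) {
    stop_rqascale("`n_scales` must be at least 4.", "invalid_spec")
  }
  if (detrend_order < 0) {
    stop_rqascale("`detrend_order` must be >= 0.", "invalid_spec")
  }
  structure(list(min_bin = as.integer(min_bin), max_bin = as.integer(max_bin),
                 n_scales = as.integer(n_scales),
                 detrend_order = as.integer(detrend_order),
                 both_ends = isTRUE(both_ends)),
            class = "dfa_config")
}

dfa_scales <- function(cfg) {
  unique(round(exp(seq(log(cfg$min_bin), log(cfg$max_bin),
                       length.out = cfg$n_scales))))
}

#' Detrended fluctuation function F(n)
#'
#' Standard DFA construction: the profile is the cumulative sum of the
#' mean-centered series; for each window size the profile is partitioned
#' into non-overlapping windows, each window is detrended by a least-squares
#' polynomial of order `detrend_order`, and `F(n)` is the root-mean-square
#' residual over all covered samples.
#'
#' @param series Numeric vector of at least `2 * min_bin` samples.
#' @param cfg A [dfa_config()].
#'
#' @return A tibble of class `dfa_fluctuation` with columns `scale` (window
#'   length) and `fluctuation` (`F(n)`).
#' @export
#' @examples
#' x <- generate_power_noise(noise_spec(alpha = 0, n = 512, seed = 1))
#' dfa_fluctuation(x, dfa_config(min_bin = 8, max_bin = 128, n_scales = 8))
dfa_fluctuation <- function(series, cfg = dfa_config()) {
  x <- check_series(series)
  stopifnot(inherits(cfg, "dfa_config"))
  if (sd(x) == 0) {
    stop_rqascale("Cannot run DFA on a constant series.", "degenerate_series")
  }
  if (length(x) < 2 * cfg$min_bin) {
    stop_rqascale("Series must be at least twice `min_bin` long.", "too_short")
  }
  prof <- cumsum(x - mean(x))
  n <- length(prof)
  scales <- dfa_scales(cfg)
  scales <- scales[scales <= n %/% 2]
  fl <- vapply(scales, function(s) {
    k <- n %/% s
    X <- stats::poly(seq_len(s), degree = max(1L, cfg$detrend_order),
                     raw = TRUE)
    X <- cbind(1, if (cfg$detrend_order >= 1) X[, seq_len(cfg$detrend_order), drop = FALSE])
    H <- X %*% solve(crossprod(X), t(X))
    rss <- function(seg) {
      y <- matrix(seg, nrow = s)
      r <- y - H %*% y
      sum(r^2)
    }
    fwd <- rss(prof[seq_len(k * s)])
    if (cfg$both_ends) {
      bwd <- rss(prof[seq.int(n - k * s + 1L, n)])
      sqrt((fwd + bwd) / (2 * k * s))
    } else {
      sqrt(fwd / (k * s))
    }
  }, numeric(1))
  structure(tibble(scale = scales, fluctuation = fl),
            class = c("dfa_fluctuation", class(tibble())))
}

#' Hurst exponent via detrended fluctuation analysis
#'
#' OLS slope of `log F(n)` against `log n` over the scale grid, reported as
#' the Hurst exponent `H`. For `1/f^alpha` noise, `H` is approximately
#' `(alpha + 1) / 2`: about 0.5 for white noise, 1.5 for Brownian-like
#' noise.
#'
#' @inheritParams dfa_fluctuation
#'
#' @return A `scaling_fit`; `slope` is `H`.
#' @export
#' @examples
#' x <- generate_power_noise(noise_spec(alpha = 0, n = 1026, seed = 1))
#' dfa_hurst(x)$slope # near 0.5
dfa_hurst <- function(series, cfg = dfa_config()) {
  fl <- dfa_fluctuation(series, cfg)
  if (any(fl$fluctuation <= 0)) {
    stop_rqascale("Zero fluctuation at some scale; cannot fit log-log line.",
                  "degenerate_scaling")
  }
  new_scaling_fit(log(fl$scale), log(fl$fluctuation), "log-log",
                  estimator = "dfa_h")
}
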