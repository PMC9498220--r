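test_that("bin-wise %REC SDs match a per-bin hand count on a toy plot", {
  set.seed(21)
  m <- random_binary_matrix(16, p = 0.2)
  cfg <- bin_scaling_config(bin_sizes = c(2, 4, 8), min_bins_per_size = 2)
  fit <- bin_sd_scaling(m, cfg)
  # enumerate the complete bins explicitly, size by size
  for (bi in seq_along(cfg$bin_sizes)) {
    b <- cfg$bin_sizes[bi]
    k <- 16 %/% b
    rates <- c()
    for (r in seq_len(k)) {
      for (cc in seq_len(k)) {
        bin <- m[((r - 1) * b + 1):(r * b), ((cc - 1) * b + 1):(cc * b)]
        rates <- c(rates, mean(bin))
      }
    }
    expect_equal(unname(exp(fit$data$y[bi])), sd(rates))
    expect_equal(unname(exp(fit$data$x[bi])), b)
  }
})

test_that("i.i.d. binary plots scale with the binomial slope of -1", {
  set.seed(22)
  m <- matrix(runif(256^2) < 0.1, 256, 256)
  fit <- bin_sd_scaling(m, bin_scaling_config(bin_sizes = 2^(1:6)))
  expect_lt(abs(fit$slope + 1), 0.1)
  expect_equal(fit$space, "log-log")
})

test_that("degenerate plots are rejected by the bin-SD estimator", {
  expect_error(bin_sd_scaling(matrix(TRUE, 64, 64)),
               class = "rqascale_degenerate_scaling")
  expect_error(bin_sd_scaling(random_binary_matrix(16),
                              bin_scaling_config(bin_sizes = c(32, 64, 128))),
               class = "rqascale_insufficient_data")
})

test_that("diagonal-profile scaling recovers exact power laws", {
  lags <- 1:50
  prof <- tibble::tibble(lag = lags, rec_rate = 0.8 / lags)
  fit <- diag_profile_scaling(prof)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  # constant profile: slope exactly 0
  fit0 <- diag_profile_scaling(tibble::tibble(lag = lags, rec_rate = 0.3))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
})

test_that("profile scaling is scale-free and drops zero-rate lags", {
  set.seed(23)
  prof <- tibble::tibble(lag = 1:40, rec_rate = exp(rnorm(40, -2, 0.3)))
  f1 <- diag_profile_scaling(prof)
  prof2 <- prof
  prof2$rec_rate <- prof2$rec_rate * 7.3
  f2 <- diag_profile_scaling(prof2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))

  prof$rec_rate[c(3, 8)] <- 0
  f3 <- diag_profile_scaling(prof)
  expect_equal(f3$n_dropped, 2L)
  expect_equal(f3$n_points, 38L)
  expect_error(diag_profile_scaling(
    tibble::tibble(lag = 1:5, rec_rate = c(0.1, 0.2, 0, 0, 0))),
    class = "rqascale_insufficient_data")
})

test_that("the lag_max fit window restricts the fitted lags", {
  prof <- tibble::tibble(lag = 1:100, rec_rate = c(0.8 / (1:50), rep(0.2, 50)))
  expect_equal(diag_profile_scaling(prof, lag_max = 50)$slope, -1,
               tolerance = 1e-10)
  expect_gt(diag_profile_scaling(prof)$slope, -1)
})

test_that("the spectral variant concentrates a cosine in one frequency bin", {
  lags <- 1:16
  prof <- tibble::tibble(lag = lags, rec_rate = 0.5 + 0.4 * cos(2 * pi * lags / 4))
  p <- prof$rec_rate - mean(prof$rec_rate)
  power <- Mod(stats::fft(p))^2 / length(p)
  pos <- power[2:9]
  expect_equal(which.max(pos), 4L)   # period 4 over 16 lags -> bin 4
  expect_gt(pos[4] / sum(pos), 0.99)
  expect_error(wk_spectrum_scaling(tibble::tibble(lag = lags, rec_rate = 0.3)),
               class = "rqascale_degenerate_spectrum")
  expect_error(wk_spectrum_scaling(prof[1:5, ]),
               class = "rqascale_insufficient_data")
})

test_that("white-noise series give a flat spectral slope on average", {
  slopes <- vapply(1:30, function(s) {
    x <- generate_power_noise(noise_spec(0, n = 1026, seed = 700 + s))
    rp <- recurrence_plot(x)
    wk_spectrum_scaling(diagonal_profile(rp), lag_max = 32)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.2)
})

test_that("consecutive-diagonal ratios behave as contracted", {
  const <- tibble::tibble(lag = 1:10, rec_rate = 0.25)
  expect_equal(as.numeric(consecutive_diag_ratio(const)), 1)
  expect_equal(as.numeric(consecutive_diag_ratio(const, orientation = "fold")), 1)
  alt <- tibble::tibble(lag = 1:4, rec_rate = c(0.2, 0.1, 0.2, 0.1))
  expect_equal(as.numeric(consecutive_diag_ratio(alt, orientation = "fold")), 2)
  # folded ratio is always >= 1, and 1 only for a constant profile;
  # the directed ratio preserves the direction of a profile decay
  set.seed(24)
  for (i in 1:10) {
    prof <- tibble::tibble(lag = 1:20, rec_rate = runif(20, 0.05, 0.5))
    expect_gt(as.numeric(consecutive_diag_ratio(prof, orientation = "fold")), 1)
  }
  expect_lt(as.numeric(consecutive_diag_ratio(
    tibble::tibble(lag = 1:2, rec_rate = c(0.4, 0.2)))), 1)
  # zero-rate members are skipped and counted
  prof <- tibble::tibble(lag = 1:5, rec_rate = c(0.2, 0, 0.2, 0.2, 0.1))
  r <- consecutive_diag_ratio(prof)
  expect_equal(attr(r, "n_pairs"), 2L)
  expect_equal(attr(r, "n_dropped"), 2L)
  expect_error(consecutive_diag_ratio(
    tibble::tibble(lag = 1:3, rec_rate = c(0.2, 0, 0.3))),
    class = "rqascale_insufficient_data")
})

test_that("estimate_all returns all six estimators and records failures", {
  x <- generate_power_noise(noise_spec(0, n = 256, seed = 31))
  est <- estimate_all(x)
  expect_named(est, c("sd_rec_slope", "lam", "diag_slope", "wk_slope",
                      "diag_ratio", "dfa_h"))
  expect_true(all(is.finite(unlist(est))))
  expect_length(attr(est, "failures"), 0)

  expect_error(estimate_all(rep(1, 256)), class = "rqascale_degenerate_series")
  expect_error(estimate_all(rnorm(32)), class = "rqascale_too_short")
})

test_that("estimate_all agrees with a step-by-step composition", {
  x <- generate_power_noise(noise_spec(1, n = 256, seed = 32))
  est <- estimate_all(x)
  n <- length(x)
  rp <- recurrence_plot(x)
  prof <- diagonal_profile(rp)
  expect_equal(est$sd_rec_slope, bin_sd_scaling(rp)$slope)
  expect_equal(est$lam, laminarity(rp))
  expect_equal(est$diag_slope, diag_profile_scaling(prof, n %/% 16)$slope)
  expect_equal(est$wk_slope, wk_spectrum_scaling(prof, max(16, n %/% 32))$slope)
  expect_equal(est$diag_ratio,
               as.numeric(consecutive_diag_ratio(prof, 6)))
  expect_equal(est$dfa_h,
               dfa_hurst(x, dfa_config(min_bin = 10, max_bin = n %/% 2))$slope)
})
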