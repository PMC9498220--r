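test_that("recurrence plots match the brute-force pairwise oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(8:32, 1)
    x <- rnorm(n)
    rp <- recurrence_plot(x, rqa_params(radius = 0.4))
    expect_identical(rp$matrix, oracle_rp(x, 0.4))
  }
  # the spec's worked raw-series example, without z-scoring
  x <- c(1, 2, 1, 2, 10)
  rp <- recurrence_plot(c(x, x), rqa_params(radius = 0.4, zscore = FALSE))
  expect_identical(rp$matrix, oracle_rp(c(x, x), 0.4, zscore = FALSE))
})

test_that("every recurrence plot is symmetric with a recurrent main diagonal", {
  set.seed(7)
  for (i in 1:20) {
    rp <- recurrence_plot(rnorm(sample(8:40, 1)))
    expect_identical(rp$matrix, t(rp$matrix))
    expect_true(all(diag(rp$matrix)))
    expect_gte(recurrence_rate(rp), 1 / rp$n)
  }
})

test_that("growing the radius never removes a recurrence", {
  set.seed(8)
  x <- rnorm(40)
  m1 <- recurrence_plot(x, rqa_params(radius = 0.3))$matrix
  m2 <- recurrence_plot(x, rqa_params(radius = 0.6))$matrix
  expect_true(all(m2[m1]))
})

test_that("degenerate and extreme inputs give the expected plots", {
  expect_error(recurrence_plot(rep(5, 20)), class = "rqascale_degenerate_series")
  # constant series without z-scoring: everything recurs
  rp <- recurrence_plot(rep(5, 20), rqa_params(radius = 0.4, zscore = FALSE))
  expect_true(all(rp$matrix))
  # spacing wider than the radius: only the main diagonal remains
  rp <- recurrence_plot(1:8) # z-scored gap 1/sd(1:8) = 0.408 > 0.4
  expect_identical(rp$matrix, diag(8) == 1)
})

test_that("recurrence rate counts cells over plots and windows", {
  rp <- recurrence_plot(1:8) # identity matrix
  expect_equal(recurrence_rate(rp), 1 / 8)
  m <- matrix(TRUE, 6, 6)
  expect_equal(recurrence_rate(m), 1)
  expect_equal(recurrence_rate(m, rows = 2:3, cols = 1:2), 1)
  set.seed(1)
  m <- random_binary_matrix(16)
  expect_equal(recurrence_rate(m, rows = 5:8, cols = 9:12),
               sum(m[5:8, 9:12]) / 16)
  expect_error(recurrence_rate(m, rows = integer(0)),
               class = "rqascale_invalid_spec")
  expect_error(recurrence_rate(m, rows = 10:20), class = "rqascale_invalid_spec")
})

test_that("laminarity matches the neighbor-count oracle", {
  expect_equal(laminarity(diag(8) == 1), 0)      # isolated diagonal points
  expect_equal(laminarity(matrix(TRUE, 8, 8)), 1)
  # hand-built pattern: an isolated point, a vertical pair, a horizontal pair
  m <- matrix(FALSE, 8, 8)
  diag(m) <- TRUE
  m[4, 2] <- TRUE                 # isolated
  m[6, 3] <- m[7, 3] <- TRUE      # vertical run of 2
  m[2, 5] <- m[2, 6] <- TRUE      # horizontal run of 2
  expect_equal(laminarity(m), oracle_laminarity(m))
  expect_equal(laminarity(m, neighbors = "both"),
               oracle_laminarity(m, neighbors = "both"))
  set.seed(12)
  for (i in 1:20) {
    m <- random_binary_matrix(sample(8:32, 1))
    expect_equal(laminarity(m), oracle_laminarity(m))
    expect_gte(laminarity(m, neighbors = "both"), laminarity(m))
  }
})

test_that("diagonal profiles match the per-diagonal loop oracle", {
  expect_true(all(diagonal_profile(diag(12) == 1)$rec_rate == 0))
  expect_true(all(diagonal_profile(matrix(TRUE, 12, 12))$rec_rate == 1))
  set.seed(13)
  for (i in 1:20) {
    m <- random_binary_matrix(sample(8:32, 1))
    p <- diagonal_profile(m, lag_max = nrow(m) - 1)
    expect_equal(p$rec_rate, oracle_diag_profile(m, p$lag))
  }
})

test_that("an exact period-3 series recurs at lags 3 and 6 only", {
  rp <- recurrence_plot(rep(c(0, 5, 10), 22))
  p <- diagonal_profile(rp, lag_max = 8)
  expect_equal(p$rec_rate[p$lag %in% c(3, 6)], c(1, 1))
  expect_equal(p$rec_rate[p$lag %in% c(1, 2)], c(0, 0))
})

test_that("profile lag windows are validated", {
  rp <- recurrence_plot(rnorm(32))
  expect_error(diagonal_profile(rp, lag_min = 0), class = "rqascale_invalid_spec")
  expect_error(diagonal_profile(rp, lag_max = 32), class = "rqascale_invalid_spec")
  expect_error(diagonal_profile(rp, lag_min = 5, lag_max = 3),
               class = "rqascale_invalid_spec")
})
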