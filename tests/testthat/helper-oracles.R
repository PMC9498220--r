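## Independent brute-force oracles. These deliberately use plain double
## loops so they share no code path with the vectorized implementation.

oracle_rp <- function(x, radius, zscore = TRUE) {
  z <- if (zscore) (x - mean(x)) / sd(x) else x
  n <- length(z)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- abs(z[i] - z[j]) <= radius
    }
  }
  m
}

oracle_laminarity <- function(m, neighbors = "vertical") {
  n <- nrow(m)
  hits <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!m[i, j]) next
      total <- total + 1L
      vert <- (i > 1 && m[i - 1, j]) || (i < n && m[i + 1, j])
      horz <- (j > 1 && m[i, j - 1]) || (j < n && m[i, j + 1])
      ok <- if (neighbors == "vertical") vert else vert || horz
      if (ok) hits <- hits + 1L
    }
  }
  hits / total
}

oracle_diag_profile <- function(m, lags) {
  n <- nrow(m)
  vapply(lags, function(d) {
    cnt <- 0L
    for (i in seq_len(n - d)) if (m[i + d, i]) cnt <- cnt + 1L
    cnt / (n - d)
  }, numeric(1))
}

## per-window lm() DFA, scale by scale
oracle_dfa_fluct <- function(x, scales, order = 1) {
  prof <- cumsum(x - mean(x))
  n <- length(prof)
  vapply(scales, function(s) {
    k <- n %/% s
    ss <- 0
    for (w in seq_len(k)) {
      seg <- prof[((w - 1) * s + 1):(w * s)]
      t <- seq_len(s)
      r <- stats::residuals(lm(seg ~ poly(t, degree = order, raw = TRUE)))
      ss <- ss + sum(r^2)
    }
    sqrt(ss / (k * s))
  }, numeric(1))
}

## log-log OLS slope of the raw periodogram (positive frequencies)
oracle_periodogram_slope <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  k <- seq_len(n %/% 2 - 1)
  pw <- p[1 + k]
  unname(coef(lm(log(pw) ~ log(k)))[2])
}

random_binary_matrix <- function(n, p = 0.3) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  m <- m | t(m)        # symmetric, like a real recurrence plot
  diag(m) <- TRUE
  m
}
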