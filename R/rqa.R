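#' Recurrence-plot parameters
#'
#' Parameters for unembedded recurrence-plot construction: the recurrence
#' threshold (radius) in z-score units, and whether the series is z-scored
#' before thresholding. Embedding dimension and delay are fixed at 1 in this
#' release, so the pairwise distance is the absolute difference of (scaled)
#' sample values, which coincides with the Euclidean distance in the
#' one-dimensional phase space.
#'
#' @param radius Recurrence threshold in units of the z-scored series;
#'   positive. The default 0.4 gives a recurrence rate near 22% for white
#'   noise.
#' @param embedding_dim,delay Must be 1 (included for forward
#'   compatibility).
#' @param zscore Z-score the series before thresholding? Default `TRUE`.
#'
#' @return An object of class `rqa_params`.
#' @export
#' @examples
#' rqa_params(radius = 0.4)
rqa_params <- function(radius = 0.4, embedding_dim = 1L, delay = 1L,
                       zscore = TRUE) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    stop_rqascale("`radius` must be a single positive number.", "invalid_spec")
  }
  if (embedding_dim != 1L || delay != 1L) {
    stop_rqascale("Only embedding_dim = 1 and delay = 1 are supported.",
                  "invalid_spec")
  }
  structure(list(radius = as.numeric(radius), embedding_dim = 1L, delay = 1L,
                 zscore = isTRUE(zscore)),
            class = "rqa_params")
}

#' @export
print.rqa_params <- function(x, ...) {
  cat(sprintf("<rqa_params> radius = %g, embedding_dim = 1, delay = 1, zscore = %s\n",
              x$radius, x$zscore))
  invisible(x)
}

#' Build an unembedded recurrence plot
#'
#' Thresholds all pairwise distances of a univariate series into an `N x N`
#' binary recurrence matrix: cell `(i, j)` is recurrent iff
#' `|z_i - z_j| <= radius`, where `z` is the (optionally z-scored) series.
#' The matrix is symmetric with an all-recurrent main diagonal (the line of
#' identity).
#'
#' @param series Numeric vector of at least 8 samples (or a
#'   single-numeric-column data frame).
#' @param params An [rqa_params()] object.
#'
#' @return An object of class `recurrence_plot`: a list with the logical
#'   `matrix`, the side length `n`, and the `params` used.
#' @export
#' @examples
#' rp <- recurrence_plot(sin(seq(0, 8 * pi, length.out = 64)))
#' recurrence_rate(rp)
recurrence_plot <- function(series, params = rqa_params()) {
  x <- check_series(series, n_min = 8)
  stopifnot(inherits(params, "rqa_params"))
  z <- if (params$zscore) zscore_series(x) else x
  m <- abs(outer(z, z, `-`)) <= params$radius
  structure(list(matrix = m, n = length(z), params = params),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> %d x %d, radius = %g, %%REC = %.3f\n",
              x$n, x$n, x$params$radius, recurrence_rate(x)))
  invisible(x)
}

as_rp_matrix <- function(rp) {
  if (inherits(rp, "recurrence_plot")) return(rp$matrix)
  if (is.matrix(rp)) {
    if (nrow(rp) != ncol(rp)) {
      stop_rqascale("Recurrence matrix must be square.", "invalid_spec")
    }
    return(rp != 0)
  }
  stop_rqascale("`rp` must be a recurrence_plot or a square binary matrix.",
                "invalid_spec")
}

#' Recurrence rate (%REC) of a plot or a rectangular window
#'
#' The proportion of recurrent cells, over the full plot or over the
#' rectangular index window `rows` x `cols`.
#'
#' @param rp A [recurrence_plot()] or a square binary matrix.
#' @param rows,cols Optional integer index vectors delimiting a rectangular
#'   region; both default to the full extent.
#'
#' @return A proportion in `[0, 1]`.
#' @export
recurrence_rate <- function(rp, rows = NULL, cols = NULL) {
  m <- as_rp_matrix(rp)
  rows <- rows %||% seq_len(nrow(m))
  cols <- cols %||% seq_len(ncol(m))
  if (length(rows) == 0 || length(cols) == 0) {
    stop_rqascale("Empty region.", "invalid_spec")
  }
  if (min(rows) < 1 || max(rows) > nrow(m) || min(cols) < 1 ||
      max(cols) > ncol(m)) {
    stop_rqascale("Region out of bounds.", "invalid_spec")
  }
  mean(m[rows, cols, drop = FALSE])
}

#' Laminarity (%LAM): recurrent points with an adjacent recurrent neighbor
#'
#' The proportion of recurrent cells `(i, j)` that have at least one
#' vertically adjacent recurrent cell `(i - 1, j)` or `(i + 1, j)` - that
#' is, membership in a vertical run of length at least 2. By the transpose
#' symmetry of an unembedded recurrence plot, this equals the
#' horizontal-run version of the statistic. `neighbors = "both"` instead
#' counts cells with a vertical *or* horizontal recurrent neighbor, a
#' strictly larger statistic. The main diagonal is included, matching a
#' whole-plot reading of the measure.
#'
#' Persistent series produce block-like recurrence structures and hence high
#' laminarity; antipersistent and white-noise series produce scattered,
#' mostly isolated recurrence points and low laminarity.
#'
#' @param rp A [recurrence_plot()] or a square binary matrix.
#' @param neighbors `"vertical"` (default) or `"both"`; see Details.
#'
#' @return A proportion in `[0, 1]`.
#' @export
laminarity <- function(rp, neighbors = c("vertical", "both")) {
  neighbors <- match.arg(neighbors)
  m <- as_rp_matrix(rp)
  n <- nrow(m)
  has_vert <- rbind(m[-1, , drop = FALSE], FALSE) |
    rbind(FALSE, m[-n, , drop = FALSE])
  hit <- if (neighbors == "vertical") {
    has_vert
  } else {
    has_vert | cbind(m[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, m[, -n, drop = FALSE])
  }
  sum(m & hit) / sum(m)
}

#' Diagonal recurrence profile
#'
#' The recurrence rate per lag: for each lag `d` (distance from the main
#' diagonal), the proportion of recurrent cells on the `d`-th subdiagonal of
#' the lower triangle, i.e. among the `N - d` cells `(i + d, i)`. The
#' profile is a model-free analogue of the autocorrelation function; the
#' main diagonal (lag 0, trivially all-recurrent) is excluded.
#'
#' @param rp A [recurrence_plot()] or a square binary matrix.
#' @param lag_min,lag_max Integer lag window, `1 <= lag_min <= lag_max <=
#'   N - 1`. `lag_max` defaults to `floor(N / 2)`, which keeps at least
#'   `N / 2` cells per diagonal and so avoids the short, noisy diagonals
#'   towards the plot corners.
#'
#' @return A tibble of class `diag_profile` with columns `lag` and
#'   `rec_rate`.
#' @export
#' @examples
#' rp <- recurrence_plot(rep(c(0, 5, 10), length.out = 66))
#' diagonal_profile(rp, lag_max = 8) # rate 1 at lags 3 and 6
diagonal_profile <- function(rp, lag_min = 1L, lag_max = NULL) {
  m <- as_rp_matrix(rp)
  n <- nrow(m)
  lag_max <- as.integer(lag_max %||% (n %/% 2))
  lag_min <- as.integer(lag_min)
  if (lag_min < 1 || lag_max > n - 1 || lag_min > lag_max) {
    stop_rqascale(sprintf("Lags must satisfy 1 <= lag_min <= lag_max <= %d.",
                          n - 1), "invalid_spec")
  }
  lags <- lag_min:lag_max
  rate <- vapply(lags, function(d) {
    ## column-major positions of the lower-triangle cells (i + d, i)
    sum(m[seq.int(d + 1L, by = n + 1L, length.out = n - d)]) / (n - d)
  }, numeric(1))
  structure(tibble(lag = lags, rec_rate = rate),
            class = c("diag_profile", class(tibble())),
            n = n)
}
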