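#' Read a univariate time series from a text or CSV file
#'
#' Plain-text input is one numeric sample per line (blank lines skipped).
#' CSV input may have a header (auto-detected); the series column is chosen
#' by name or index, defaulting to the first numeric column.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @param column For CSV: column name or index; `NULL` picks the first
#'   numeric column.
#'
#' @return Numeric vector of samples.
#' @export
read_series <- function(path, format = c("auto", "txt", "csv"), column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_rqascale(sprintf("File not found: %s", path), "io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  if (format == "txt") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(trimws(lines) != "")
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      bad <- keep[which(is.na(vals))[1]]
      stop_rqascale(sprintf("Non-numeric value at line %d of %s: '%s'",
                            bad, path, trimws(lines[bad])), "parse")
    }
    return(vals)
  }
  first <- readLines(path, n = 1, warn = FALSE)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(trimws(fields))))
  df <- utils::read.csv(path, header = has_header, blank.lines.skip = TRUE,
                        stringsAsFactors = FALSE)
  col <- if (is.null(column)) {
    num <- which(vapply(df, is.numeric, logical(1)))
    if (length(num) == 0) {
      ## no fully-numeric column: report the first offending cell
      v <- suppressWarnings(as.numeric(df[[1]]))
      bad <- which(is.na(v))[1]
      stop_rqascale(sprintf("Non-numeric value at line %d of %s",
                            bad + has_header, path), "parse")
    }
    num[1]
  } else if (is.character(column)) {
    if (!column %in% names(df)) {
      stop_rqascale(sprintf("No column '%s' in %s", column, path), "io")
    }
    column
  } else {
    as.integer(column)
  }
  v <- df[[col]]
  if (!is.numeric(v)) {
    parsed <- suppressWarnings(as.numeric(v))
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1]
      stop_rqascale(sprintf("Non-numeric value at line %d of %s: '%s'",
                            bad + has_header, path, v[bad]), "parse")
    }
    v <- parsed
  }
  if (anyNA(v)) {
    stop_rqascale(sprintf("Missing value in column of %s", path), "parse")
  }
  v
}

config_as_list <- function(config) {
  list(alpha_grid = config$alpha_grid, reps = config$reps, n = config$n,
       conditions = config$conditions,
       noise_sd_fraction = config$noise_sd_fraction, seed = config$seed,
       radius = config$rqa$radius, zscore = config$rqa$zscore,
       bin_sizes = config$bins$bin_sizes,
       min_bins_per_size = config$bins$min_bins_per_size,
       dfa_min_bin = config$dfa$min_bin, dfa_max_bin = config$dfa$max_bin,
       dfa_n_scales = config$dfa$n_scales,
       dfa_detrend_order = config$dfa$detrend_order)
}

#' Write simulation results with full provenance
#'
#' CSV output is the long-format records table preceded by `#`-prefixed
#' provenance comments (one per configuration field, deterministic order);
#' JSON output nests `config` and `records`. Either file contains enough
#' configuration to regenerate the run exactly.
#'
#' @param results An `rqa_sim` from [run_simulation()] (or a non-empty
#'   records tibble, written without provenance).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#'
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  is_sim <- inherits(results, "rqa_sim")
  records <- if (is_sim) results$records else results
  if (is.null(records) || nrow(records) == 0) {
    stop_rqascale("Refusing to write empty results.", "invalid_spec")
  }
  cfg <- if (is_sim) config_as_list(results$config) else NULL
  if (format == "json") {
    payload <- list(records = records)
    if (!is.null(cfg)) payload <- c(list(config = cfg), payload)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(cfg)) {
      for (key in names(cfg)) {
        writeLines(sprintf("# %s: %s", key,
                           paste(cfg[[key]], collapse = ",")), con)
      }
    }
    utils::write.csv(records, con, row.names = FALSE)
  }
  invisible(path)
}

#' Export a recurrence matrix as plain text
#'
#' Dense 0/1 matrix, one row per line, values separated by single spaces.
#'
#' @param rp A [recurrence_plot()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_rp_matrix <- function(rp, path) {
  m <- as_rp_matrix(rp)
  writeLines(apply(m + 0L, 1, paste, collapse = " "), path)
  invisible(path)
}
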