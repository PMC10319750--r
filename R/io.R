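# Flat-file configuration and results I/O.

#' Read a flat key/value configuration file
#'
#' Parses lines of the form `key = value` or `key: value`; blank lines and
#' `#` comments are ignored, and values that parse as numbers are returned
#' numeric.  Recognised model keys: `alpha`, `beta`, `delta1`, `delta2`,
#' `gamma1`, `gamma2`, `hbar_tilde`, `t_max`, `n_steps`, `seed` (unknown keys
#' are passed through untouched).
#'
#' @param path path to the configuration file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'")
    key <- trimws(m[2L])
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a results table to CSV or JSON
#'
#' CSV output formats every numeric column with 17 significant digits so the
#' file round-trips binary doubles losslessly; JSON output wraps the table in
#' an object with a `metadata` block echoing the parameters that produced it.
#' An empty table is an error and no file is created.
#'
#' @param table a non-empty `data.frame`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param metadata named list recorded in the JSON `metadata` block (ignored
#'   for CSV).
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(table, path, format = c("csv", "json"),
                          metadata = list()) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty data.frame; no file written")
  if (format == "csv") {
    fmt <- table
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
    utils::write.table(fmt, path, sep = ",", dec = ".", row.names = FALSE,
                       col.names = TRUE, quote = TRUE)
  } else {
    jsonlite::write_json(list(metadata = metadata, data = table), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path path to the file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return for CSV, the `data.frame`; for JSON, a list with elements
#'   `metadata` and `data` (a `data.frame`).
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::read.csv(path, check.names = FALSE)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$data <- as.data.frame(x$data)
    x
  }
}
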