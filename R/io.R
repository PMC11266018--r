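# Delimited-text interfaces: time-series tables and result rows.

#' Read complex series from a delimited table
#'
#' Reads a CSV/TSV table with one column per channel and a header row.
#' Magnitude and phase columns are paired by the naming convention
#' `<name>_mag` / `<name>_phase`; every complete pair becomes one
#' [complex_series()].
#'
#' @param path File path.
#' @param sep Field separator; `","` default, use `"\t"` for TSV.
#' @return Named list of `complex_series`.
#' @seealso [write_series_table()]
#' @export
read_series_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("empty series table: ", path, call. = FALSE)
  cn <- names(df)
  mags <- grep("_mag$", cn, value = TRUE)
  out <- list()
  for (m in mags) {
    base <- sub("_mag$", "", m)
    ph <- paste0(base, "_phase")
    if (!ph %in% cn) {
      warning("column ", m, " has no matching ", ph, "; skipped")
      next
    }
    out[[base]] <- complex_series(df[[m]], df[[ph]])
  }
  if (length(out) == 0L)
    stop("no *_mag / *_phase column pairs found in ", path, call. = FALSE)
  out
}

#' Write complex series to a delimited table
#'
#' Inverse of [read_series_table()]: writes one `<name>_mag` and one
#' `<name>_phase` column per series.
#'
#' @param series Named list of [complex_series()], all the same length.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_series_table <- function(series, path, sep = ",") {
  stopifnot(is.list(series), length(series) > 0L)
  if (is.null(names(series)))
    names(series) <- paste0("s", seq_along(series))
  cols <- list()
  for (nm in names(series)) {
    z <- series[[nm]]
    stopifnot(inherits(z, "complex_series"))
    cols[[paste0(nm, "_mag")]] <- z$magnitude
    cols[[paste0(nm, "_phase")]] <- z$phase
  }
  utils::write.table(as.data.frame(cols), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write causality results as CSV
#'
#' One row per result with columns `pair_id`, `estimator`, `tau`,
#' `delta_c_mean`, `p_value`, `direction`. Configuration provenance
#' (estimator settings, seed) is embedded as leading `#` comment lines.
#'
#' @param results A `cvte_causality` or list of them.
#' @param path Output file path.
#' @param pair_ids Optional identifiers, recycled along results.
#' @param config Optional named list written into the header comments.
#' @export
write_causality_csv <- function(results, path, pair_ids = NULL,
                                config = NULL) {
  if (inherits(results, "cvte_causality")) results <- list(results)
  if (is.null(pair_ids)) pair_ids <- seq_along(results)
  rows <- do.call(rbind, Map(function(r, id)
    as.data.frame(r, pair_id = id), results, pair_ids))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (nm in names(config))
      writeLines(paste0("# ", nm, " = ",
                        paste(config[[nm]], collapse = " ")), con)
  }
  utils::write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
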