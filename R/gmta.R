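#' Read a global mean temperature anomaly (GMTA) series
#'
#' Parses a two-column CSV (`year`, `anomaly_c`) of annual global mean
#' temperature anomalies in degrees Celsius relative to the 1951-1980
#' reference mean, and tags every year with its provenance. Two sources are
#' composited in practice: the instrumental record (1880 onwards) and a
#' pre-instrumental reconstruction derived from glacier-length records.
#'
#' @param path CSV file with columns `year`, `anomaly_c`.
#' @param source Provenance tag, `"instrumental"` or `"reconstructed"`.
#' @return A `gmta_series` tibble: `year`, `anomaly_c`, `source`.
#' @export
read_gmta <- function(path, source = c("instrumental", "reconstructed")) {
  source <- match.arg(source)
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("year", "anomaly_c") %in% names(raw))) {
    rlang::abort(sprintf("%s: expected columns year, anomaly_c.", path))
  }
  if (nrow(raw) == 0) rlang::abort(sprintf("%s: empty GMTA file.", path))
  year <- suppressWarnings(as.integer(raw$year))
  anom <- suppressWarnings(as.numeric(raw$anomaly_c))
  bad <- which(is.na(year) | is.na(anom))
  if (length(bad) > 0) {
    # +1: header line of the CSV
    rlang::abort(sprintf("%s: non-numeric year/anomaly at line %d.",
                         path, bad[1] + 1L))
  }
  new_gmta_series(year, anom, source)
}

new_gmta_series <- function(year, anomaly_c, source) {
  if (anyDuplicated(year) > 0) {
    rlang::abort(sprintf("Duplicated year(s) in GMTA series: %s",
                         paste(unique(year[duplicated(year)]), collapse = ", ")))
  }
  out <- tibble::tibble(year = as.integer(year),
                        anomaly_c = as.numeric(anomaly_c),
                        source = as.character(source)) |>
    dplyr::arrange(.data$year)
  class(out) <- c("gmta_series", class(out))
  out
}

#' Composite an instrumental and a reconstructed GMTA series
#'
#' Joins the two sources into one contiguous annual series. Wherever both
#' cover a year the instrumental value wins; the union of years must have no
#' gaps.
#'
#' @param instrumental,reconstruction `gmta_series` tibbles (see
#'   [read_gmta()]).
#' @return A `gmta_series` covering the union of years, per-year `source`
#'   tags preserved.
#' @export
composite_gmta <- function(instrumental, reconstruction) {
  keep <- reconstruction[!(reconstruction$year %in% instrumental$year), ]
  out <- dplyr::bind_rows(instrumental, keep) |> dplyr::arrange(.data$year)
  yrs <- out$year
  gaps <- setdiff(seq(min(yrs), max(yrs)), yrs)
  if (length(gaps) > 0) {
    rlang::abort(sprintf("Composite GMTA series has gap year(s): %s",
                         paste(gaps, collapse = ", ")))
  }
  class(out) <- c("gmta_series", class(out))
  out
}

#' Look up anomalies for given years
#'
#' Exact annual lookup, no interpolation: GMTA is an annual global index and
#' cannot resolve finer temporal structure.
#'
#' @param series A `gmta_series`.
#' @param years Integer vector of years, all within the series range.
#' @return Numeric vector of anomalies (degrees C) in the order of `years`.
#' @export
gmta_anomaly <- function(series, years) {
  idx <- match(years, series$year)
  if (anyNA(idx)) {
    rlang::abort(sprintf("Year(s) outside the GMTA series: %s",
                         paste(unique(years[is.na(idx)]), collapse = ", ")))
  }
  series$anomaly_c[idx]
}

#' Write a GMTA series to CSV
#'
#' @param series A `gmta_series`.
#' @param path Output CSV path (`year, anomaly_c, source`).
#' @return `path`, invisibly.
#' @export
write_gmta <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  invisible(path)
}
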