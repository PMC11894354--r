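#' Read a timestamped IBI stream
#'
#' Reads an interbeat-interval stream from CSV (header
#' `timestamp_ms,ibi_ms`) or JSON (array of `{"t": <ms>, "ibi": <ms>}`
#' objects). Samples are sorted by timestamp; duplicate timestamps are
#' collapsed to the first occurrence with a warning.
#'
#' @param path File path.
#' @param participant_id Participant label attached to every sample.
#' @param device `"ppg"` or `"ecg"`.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return A tibble with columns `participant_id`, `device`, `timestamp_ms`,
#'   `ibi_ms`, sorted by strictly increasing timestamp.
#' @export
read_ibi <- function(path, participant_id, device = c("ppg", "ecg"),
                     format = c("auto", "csv", "json")) {
  device <- match.arg(device)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))

  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    if (nrow(raw) == 0) abort(sprintf("Empty IBI file: %s", path))
    if (!all(c("timestamp_ms", "ibi_ms") %in% names(raw))) {
      abort("IBI CSV must have columns `timestamp_ms` and `ibi_ms`.")
    }
    ts <- suppressWarnings(as.numeric(raw$timestamp_ms))
    ib <- suppressWarnings(as.numeric(raw$ibi_ms))
    bad <- which(!is.finite(ts) | !is.finite(ib))
    if (length(bad)) {
      abort(sprintf("Malformed IBI row at line %d of %s", bad[1] + 1L, path))
    }
  } else {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(rec) == 0 || NROW(rec) == 0) abort(sprintf("Empty IBI file: %s", path))
    if (!all(c("t", "ibi") %in% names(rec))) {
      abort("IBI JSON must be an array of {\"t\", \"ibi\"} objects.")
    }
    ts <- suppressWarnings(as.numeric(rec$t))
    ib <- suppressWarnings(as.numeric(rec$ibi))
    bad <- which(!is.finite(ts) | !is.finite(ib))
    if (length(bad)) abort(sprintf("Malformed IBI record %d in %s", bad[1], path))
  }
  new_ibi_series(participant_id, device, ts, ib)
}

# shared validation: sort, collapse duplicate timestamps (keep first)
new_ibi_series <- function(participant_id, device, ts, ib) {
  if (any(ib <= 0)) abort("IBI values must be positive.")
  if (is.unsorted(ts)) {
    warn("IBI samples out of order; sorting by timestamp.")
    o <- order(ts)
    ts <- ts[o]
    ib <- ib[o]
  }
  dup <- duplicated(ts)
  if (any(dup)) {
    warn(sprintf("%d duplicate timestamp(s) collapsed to first occurrence.", sum(dup)))
    ts <- ts[!dup]
    ib <- ib[!dup]
  }
  tibble::tibble(
    participant_id = participant_id, device = device,
    timestamp_ms = ts, ibi_ms = ib
  )
}

#' Write an IBI stream
#'
#' Counterpart of [read_ibi()]; writes `timestamp_ms,ibi_ms` CSV or an array
#' of `{"t", "ibi"}` JSON objects.
#'
#' @param series IBI tibble (from [read_ibi()] or [generate_ibi_series()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; defaults from the extension.
#' @return `path`, invisibly.
#' @export
write_ibi <- function(series, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(
      dplyr::select(series, "timestamp_ms", "ibi_ms"), path)
  } else {
    jsonlite::write_json(
      data.frame(t = series$timestamp_ms, ibi = series$ibi_ms),
      path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Remove artifact beats
#'
#' Flags and removes IBI artifacts: values above 1500 ms or below 300 ms.
#' The inequalities are strict, so boundary values of exactly 300 or 1500 ms
#' are retained.
#'
#' @param series IBI tibble.
#' @return The filtered tibble with attribute `removed_count`; retrieve it
#'   with `attr(x, "removed_count")` or [artifact_summary()].
#' @export
#' @examples
#' x <- tibble::tibble(participant_id = "P01", device = "ppg",
#'                     timestamp_ms = c(0, 800, 1600), ibi_ms = c(250, 800, 1600))
#' filter_artifacts(x)
filter_artifacts <- function(series) {
  keep <- series$ibi_ms >= 300 & series$ibi_ms <= 1500
  out <- series[keep, , drop = FALSE]
  attr(out, "removed_count") <- sum(!keep)
  out
}

#' Summarise artifact removal
#'
#' @param filtered Result of [filter_artifacts()].
#' @return A one-row tibble with `kept` and `removed` counts.
#' @export
artifact_summary <- function(filtered) {
  tibble::tibble(
    kept = nrow(filtered),
    removed = attr(filtered, "removed_count") %||% 0L
  )
}

#' Read per-minute step counts
#'
#' CSV with header `minute_start_ms,steps`. Records are sorted; missing
#' minutes are preserved as gaps (no imputation). Negative step values are
#' rejected.
#'
#' @param path File path.
#' @param participant_id Participant label.
#' @return A tibble with columns `participant_id`, `minute_start_ms`, `steps`.
#' @export
read_steps <- function(path, participant_id) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = "dd")
  if (!all(c("minute_start_ms", "steps") %in% names(raw))) {
    abort("Step CSV must have columns `minute_start_ms` and `steps`.")
  }
  if (any(!is.finite(raw$minute_start_ms) | !is.finite(raw$steps))) {
    abort(sprintf("Malformed step row in %s", path))
  }
  if (any(raw$steps < 0)) abort("Negative step counts are not valid.")
  raw <- raw[order(raw$minute_start_ms), ]
  tibble::tibble(
    participant_id = participant_id,
    minute_start_ms = raw$minute_start_ms,
    steps = as.integer(raw$steps)
  )
}

#' Write per-minute step counts
#'
#' @param steps Step tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(steps, path) {
  readr::write_csv(dplyr::select(steps, "minute_start_ms", "steps"), path)
  invisible(path)
}
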