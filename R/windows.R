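#' Partition an IBI stream into wall-clock 5-minute windows
#'
#' Every sample is assigned to exactly one window by
#' `floor(timestamp / 300000)`, so windows start at real-time 5-minute marks
#' (12:00, 12:05, ...). Windows containing no samples are not emitted.
#' The expected-data-fraction QC statistic assumes 60 beats/min, i.e. 300
#' expected points per window, and is capped at 100% because faster heart
#' rates can exceed that count.
#'
#' @param series IBI tibble (one participant/device, artifact-filtered).
#' @return A tibble with one row per non-empty window: `participant_id`,
#'   `device`, `window_start_ms`, `samples` (list column of
#'   `timestamp_ms`/`ibi_ms` tibbles), `n_points`, `expected_fraction_pct`.
#' @export
segment_windows <- function(series) {
  if (nrow(series) == 0) {
    return(tibble::tibble(
      participant_id = character(), device = character(),
      window_start_ms = numeric(), samples = list(),
      n_points = integer(), expected_fraction_pct = numeric()
    ))
  }
  series |>
    dplyr::mutate(window_start_ms = floor(.data$timestamp_ms / WINDOW_MS) * WINDOW_MS) |>
    dplyr::group_by(.data$participant_id, .data$device, .data$window_start_ms) |>
    tidyr::nest(samples = c("timestamp_ms", "ibi_ms")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n_points = purrr::map_int(.data$samples, nrow),
      expected_fraction_pct = expected_data_fraction(.data$n_points)
    ) |>
    dplyr::arrange(.data$participant_id, .data$device, .data$window_start_ms)
}

#' Expected data fraction of a window
#'
#' `100 * n_points / 300`, capped at 100.
#'
#' @param n_points Number of IBI samples in the window (vectorised).
#' @return Percentage in \[0, 100\].
#' @export
expected_data_fraction <- function(n_points) {
  pmin(100, 100 * n_points / EXPECTED_POINTS)
}

#' Participant-level wear-compliance QC
#'
#' The participant's expected data fraction is the total observed point count
#' over the monitoring span divided by 300 times the number of 5-minute slots
#' in the span -- counting empty slots between the first and last observed
#' window -- times 100. Participants below the threshold are flagged for
#' exclusion.
#'
#' @param windows Window tibble from [segment_windows()] (one
#'   participant/device).
#' @param threshold Inclusion threshold, percent (default 70).
#' @return A one-row tibble: `participant_id`, `device`, `total_windows`
#'   (non-empty), `usable_windows` (if [find_gaps()] has been applied,
#'   otherwise `NA`), `participant_expected_fraction`, `included`.
#' @export
participant_inclusion <- function(windows, threshold = 70) {
  if (nrow(windows) == 0) abort("No windows: cannot assess inclusion.")
  span_slots <- (max(windows$window_start_ms) - min(windows$window_start_ms)) /
    WINDOW_MS + 1
  frac <- min(100, 100 * sum(windows$n_points) / (EXPECTED_POINTS * span_slots))
  tibble::tibble(
    participant_id = windows$participant_id[1],
    device = windows$device[1],
    total_windows = nrow(windows),
    usable_windows = if ("usable" %in% names(windows)) {
      sum(windows$usable)
    } else NA_integer_,
    participant_expected_fraction = frac,
    included = frac >= threshold
  )
}

# gap scan for one window's samples; times in ms. Returns gap intervals
# (consecutive-difference > threshold, window edges included), the longest
# continuous segment in wall-clock terms (earlier one on ties), and the
# usable flag (> 3 gaps or < 2 samples disqualifies the window).
scan_gaps <- function(timestamp_ms, window_start_ms, gap_threshold_s = 15) {
  w0 <- window_start_ms
  w1 <- window_start_ms + WINDOW_MS
  thr <- gap_threshold_s * 1000
  if (length(timestamp_ms) < 2) {
    return(list(gaps = tibble::tibble(gap_start_ms = numeric(), gap_end_ms = numeric()),
                usable_start_ms = NA_real_, usable_end_ms = NA_real_,
                n_gaps = NA_integer_, usable = FALSE))
  }
  bounds <- c(w0, timestamp_ms, w1)
  d <- diff(bounds)
  is_gap <- d > thr
  gaps <- tibble::tibble(
    gap_start_ms = bounds[-length(bounds)][is_gap],
    gap_end_ms = bounds[-1][is_gap]
  )
  # segments between gaps (and window edges); a sample on a gap boundary
  # belongs to the segment on its own side
  seg_start <- c(w0, gaps$gap_end_ms)
  seg_end <- c(gaps$gap_start_ms, w1)
  ok <- seg_end > seg_start
  seg_start <- seg_start[ok]
  seg_end <- seg_end[ok]
  if (length(seg_start) == 0) {
    best <- c(NA_real_, NA_real_)
  } else {
    i <- which.max(seg_end - seg_start) # which.max takes the first (earlier) tie
    best <- c(seg_start[i], seg_end[i])
  }
  list(
    gaps = gaps,
    usable_start_ms = best[1], usable_end_ms = best[2],
    n_gaps = nrow(gaps),
    usable = nrow(gaps) <= 3
  )
}

#' Detect signal gaps and the longest usable segment per window
#'
#' A gap is a consecutive-timestamp difference strictly greater than the
#' threshold (default 15 s); the intervals from the window start to the first
#' sample and from the last sample to the window end count as gaps too. When
#' gaps are present, frequency-domain metrics are computed on the longest
#' continuous segment only (the earlier one on ties); a window with more than
#' 3 such gaps, or fewer than 2 samples, is unusable for frequency-domain
#' analysis.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param gap_threshold_s Gap threshold in seconds (default 15).
#' @return `windows` with added columns `gaps` (list of gap-interval
#'   tibbles), `n_gaps`, `usable_start_ms`, `usable_end_ms`, `usable`.
#' @export
find_gaps <- function(windows, gap_threshold_s = 15) {
  res <- purrr::map2(windows$samples, windows$window_start_ms,
                     ~ scan_gaps(.x$timestamp_ms, .y, gap_threshold_s))
  windows |>
    dplyr::mutate(
      gaps = purrr::map(res, "gaps"),
      n_gaps = purrr::map_int(res, ~ .x$n_gaps %||% NA_integer_),
      usable_start_ms = purrr::map_dbl(res, "usable_start_ms"),
      usable_end_ms = purrr::map_dbl(res, "usable_end_ms"),
      usable = purrr::map_lgl(res, "usable")
    )
}

#' Classify window activity from step counts
#'
#' Averages the step records whose minute start falls inside the window. At
#' least 2 overlapping records are required; otherwise the activity is
#' `"unknown"`. Mean steps of exactly 0 is `"rest"`, anything positive below
#' 100 steps/min is `"light"`, and 100 or more is `"high"` (such windows had
#' no analogue in free-living smartwatch cohorts and are excluded from the
#' standard contrasts).
#'
#' @param windows Window tibble from [segment_windows()].
#' @param steps Step tibble (same participant).
#' @return `windows` with added columns `activity` and `mean_steps`.
#' @export
classify_activity <- function(windows, steps) {
  cls <- purrr::map(windows$window_start_ms, function(w0) {
    s <- steps$steps[steps$minute_start_ms >= w0 &
                       steps$minute_start_ms < w0 + WINDOW_MS]
    if (length(s) < 2) {
      list(activity = "unknown", mean_steps = NA_real_)
    } else {
      m <- mean(s)
      list(
        activity = if (m == 0) "rest" else if (m < 100) "light" else "high",
        mean_steps = m
      )
    }
  })
  windows |>
    dplyr::mutate(
      activity = purrr::map_chr(cls, "activity"),
      mean_steps = purrr::map_dbl(cls, "mean_steps")
    )
}
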