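#' Time-domain HRV metrics of one window
#'
#' Median IBI, STDRR (sample SD of the IBI values) and RMSDRR (root mean
#' square of successive IBI differences), computed over all samples in the
#' window.
#'
#' @param ibi Numeric vector of IBI values (ms) in timestamp order.
#' @return One-row tibble with `median_ibi`, `stdrr`, `rmsdrr`,
#'   `time_valid`. Fewer than 2 samples gives `time_valid = FALSE`.
#' @export
#' @examples
#' time_domain(c(790, 810))
time_domain <- function(ibi) {
  if (length(ibi) < 2) {
    return(tibble::tibble(median_ibi = NA_real_, stdrr = NA_real_,
                          rmsdrr = NA_real_, time_valid = FALSE))
  }
  tibble::tibble(
    median_ibi = median(ibi),
    stdrr = sd(ibi),
    rmsdrr = sqrt(mean(diff(ibi)^2)),
    time_valid = TRUE
  )
}

#' Resample an IBI segment to a uniform grid with PCHIP
#'
#' Shape-preserving piecewise cubic Hermite interpolation through the
#' `(timestamp, ibi)` samples of the usable segment, evaluated on a uniform
#' grid (default 5 Hz) tiling `[usable_start, usable_end)`. The interpolant
#' reproduces the original values at the original sample times and does not
#' overshoot between knots. Where the segment extends past the outermost
#' samples (edge gaps no longer than the gap threshold), the boundary value
#' is held constant rather than extrapolated.
#'
#' @param samples Tibble with `timestamp_ms`, `ibi_ms`.
#' @param usable_start_ms,usable_end_ms Segment bounds from [find_gaps()].
#' @param rate_hz Resampling rate, Hz (default 5).
#' @param min_duration_s Minimum segment duration (default 60 s, one LF
#'   sub-window).
#' @return Tibble with `time_ms` and `value`, or `NULL` when the segment has
#'   fewer than 4 samples or is shorter than `min_duration_s`.
#' @export
resample_pchip <- function(samples, usable_start_ms, usable_end_ms,
                           rate_hz = 5, min_duration_s = 60) {
  if (is.na(usable_start_ms) || is.na(usable_end_ms)) return(NULL)
  inside <- samples$timestamp_ms >= usable_start_ms &
    samples$timestamp_ms <= usable_end_ms
  x <- samples$timestamp_ms[inside]
  y <- samples$ibi_ms[inside]
  if (length(x) < 4) return(NULL)
  if ((usable_end_ms - usable_start_ms) < min_duration_s * 1000) return(NULL)

  step <- 1000 / rate_hz
  n_grid <- floor((usable_end_ms - usable_start_ms) / step)
  grid <- usable_start_ms + step * (seq_len(n_grid) - 1)

  # hold boundary values across sub-threshold edge gaps
  if (usable_start_ms < x[1]) {
    x <- c(usable_start_ms, x)
    y <- c(y[1], y)
  }
  if (usable_end_ms > x[length(x)]) {
    x <- c(x, usable_end_ms)
    y <- c(y, y[length(y)])
  }
  tibble::tibble(time_ms = grid, value = pracma::pchip(x, y, grid))
}

#' Zero-phase band-pass filter of a resampled IBI signal
#'
#' Removes the mean, then applies a 4th-order Butterworth band-pass
#' (two second-order sections, forward-backward so the output is zero-phase
#' and stays aligned with the variance sub-windows). Pass bands are the
#' conventional LF band 0.04--0.15 Hz and an HF band widened to 0.15--1.0 Hz
#' so that elevated breathing rates during activity stay in band.
#'
#' @param values Uniformly sampled signal values.
#' @param band `"lf"` or `"hf"`, or a numeric length-2 vector of band edges
#'   in Hz.
#' @param rate_hz Sampling rate of `values`, Hz.
#' @return Filtered values, same length as the input.
#' @export
band_filter <- function(values, band = c("lf", "hf"), rate_hz = 5) {
  edges <- if (is.numeric(band)) band else
    switch(match.arg(band), lf = c(0.04, 0.15), hf = c(0.15, 1.0))
  flt <- signal::butter(2, edges / (rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, values - mean(values)))
}

#' Per-sub-window log-variance candidates
#'
#' Tiles the filtered signal into consecutive non-overlapping sub-windows of
#' `subwindow_s` seconds (60 s for LF, 30 s for HF), dropping a partial
#' trailing sub-window, and returns `ln(variance)` of each (population
#' variance, units ms^2). Zero variance gives `-Inf`, which the censoring
#' step removes.
#'
#' @param values Filtered signal values.
#' @param subwindow_s Sub-window length, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @return Numeric vector of candidate ln-variance values (possibly empty).
#' @export
ln_variance_candidates <- function(values, subwindow_s, rate_hz = 5) {
  len <- as.integer(subwindow_s * rate_hz)
  n_sub <- length(values) %/% len
  if (n_sub == 0) return(numeric())
  vapply(seq_len(n_sub), function(k) {
    seg <- values[((k - 1) * len + 1):(k * len)]
    log(mean((seg - mean(seg))^2))
  }, numeric(1))
}

#' Censored median of log-variance candidates
#'
#' Candidates below `censor[1]` (default 2.5) or above `censor[2]`
#' (default 9.0) are eliminated; the median of the survivors represents the
#' 5-minute window. With no survivors the result is `NA`.
#'
#' @param candidates Numeric vector from [ln_variance_candidates()].
#' @param censor Length-2 numeric, lower and upper censoring bounds.
#' @return Scalar median of surviving values, or `NA_real_`.
#' @export
#' @examples
#' censored_median(c(3, 4, 10, 5, 2)) # 4
censored_median <- function(candidates, censor = c(2.5, 9.0)) {
  keep <- candidates >= censor[1] & candidates <= censor[2]
  if (!any(keep)) return(NA_real_)
  median(candidates[keep])
}

#' Band power of a filtered signal
#'
#' Convenience composition of [ln_variance_candidates()] (60-s sub-windows
#' for LF, 30-s for HF) and [censored_median()].
#'
#' @inheritParams band_filter
#' @param values Band-filtered signal values.
#' @param censor Censoring bounds for the ln-variance candidates.
#' @return Scalar band power (median censored ln-variance) or `NA_real_`.
#' @export
band_power <- function(values, band = c("lf", "hf"), rate_hz = 5,
                       censor = c(2.5, 9.0)) {
  band <- match.arg(band)
  sub_s <- if (band == "lf") 60 else 30
  censored_median(ln_variance_candidates(values, sub_s, rate_hz), censor)
}

# frequency-domain metrics for one window row; returns list(lf, hf)
freq_domain_one <- function(samples, usable_start_ms, usable_end_ms, usable,
                            rate_hz, censor) {
  out <- list(lf = NA_real_, hf = NA_real_)
  if (!isTRUE(usable)) return(out)
  rs <- resample_pchip(samples, usable_start_ms, usable_end_ms, rate_hz)
  if (is.null(rs)) return(out)
  out$lf <- band_power(band_filter(rs$value, "lf", rate_hz), "lf", rate_hz, censor)
  out$hf <- band_power(band_filter(rs$value, "hf", rate_hz), "hf", rate_hz, censor)
  out
}

#' Compute all six HRV metrics per window
#'
#' Time-domain metrics (median IBI, STDRR, RMSDRR) are computed on all
#' samples in each window; frequency-domain metrics (LF, HF and their ratio
#' LF/HF) are computed on the longest continuous segment after the gap rule,
#' via PCHIP resampling to 5 Hz, zero-phase band-pass filtering, and the
#' median of censored ln-variance sub-windows (60 s for LF, 30 s for HF,
#' censored outside \[2.5, 9.0\]). Failures are recorded in the
#' `time_valid`/`freq_valid` flags, never raised, so cohort runs complete.
#'
#' @param windows Window tibble from [segment_windows()]; [find_gaps()] is
#'   applied automatically if its columns are absent.
#' @param gap_threshold_s Gap threshold, seconds (default 15).
#' @param rate_hz Resampling rate, Hz (default 5).
#' @param censor Ln-variance censoring bounds (default `c(2.5, 9.0)`).
#' @return `windows` with added columns `median_ibi`, `stdrr`, `rmsdrr`,
#'   `lf`, `hf`, `lf_hf`, `time_valid`, `freq_valid`.
#' @export
compute_hrv <- function(windows, gap_threshold_s = 15, rate_hz = 5,
                        censor = c(2.5, 9.0)) {
  if (!"usable" %in% names(windows)) {
    windows <- find_gaps(windows, gap_threshold_s)
  }
  td <- purrr::map_dfr(windows$samples, ~ time_domain(.x$ibi_ms))
  fd <- purrr::pmap(
    list(windows$samples, windows$usable_start_ms, windows$usable_end_ms,
         windows$usable),
    freq_domain_one, rate_hz = rate_hz, censor = censor
  )
  windows |>
    dplyr::mutate(
      median_ibi = td$median_ibi,
      stdrr = td$stdrr,
      rmsdrr = td$rmsdrr,
      time_valid = td$time_valid,
      lf = purrr::map_dbl(fd, "lf"),
      hf = purrr::map_dbl(fd, "hf"),
      lf_hf = .data$lf / .data$hf,
      freq_valid = is.finite(.data$lf) & is.finite(.data$hf)
    )
}

#' Flatten a window-metric table for export
#'
#' Drops the list columns, keeping the per-window metric record that the
#' CSV writers and the statistical stage consume.
#'
#' @param metrics Result of [compute_hrv()].
#' @return A plain tibble (no list columns).
#' @export
metrics_table <- function(metrics) {
  keep <- intersect(
    c("participant_id", "device", "window_start_ms", "level", "activity",
      "mean_steps", "n_points", "expected_fraction_pct", "n_gaps",
      "median_ibi", "stdrr", "rmsdrr", "lf", "hf", "lf_hf",
      "time_valid", "freq_valid"),
    names(metrics)
  )
  dplyr::select(metrics, dplyr::all_of(keep))
}
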